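---
title: "Gene-based association testing from summary-level eQTL reference data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based association testing from summary-level eQTL reference data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A transcriptome-wide association study (TWAS) tests whether the genetically
regulated component of a gene's expression (GReX) is associated with a trait.
The classical two-stage design first fits a multivariable model
$e_g = X_g w + \epsilon_g$ on an expression reference panel (Stage I), then
uses the fitted cis-eQTL weights $\hat{w}$ to impute GReX in a GWAS cohort and
tests GReX–trait association (Stage II). Stage I normally requires
individual-level genotypes and expression. Large consortium resources,
however, release only *summary-level* eQTL statistics — per-SNP marginal
effects and p-values from the single-variant model $e_g = x_j w_j +
\epsilon_j$. This package trains Stage-I weights directly from such summary
statistics plus an external LD reference panel, by treating the eQTL summary
data exactly like GWAS summary data in a polygenic-score calculation, and
then carries out Stage II from GWAS summary statistics alone.

Because the genetic architecture of expression (how many cis-SNPs are causal,
and how much variance they explain) is unknown a priori, no single estimator
dominates. The package therefore trains four complementary estimators and
combines their per-gene association p-values into one omnibus p-value with
the aggregated Cauchy combination (ACAT), which is robust to the strong
dependence among the tests.

## The summary-statistic identities

With column-standardized genotypes and expression, the marginal effects and
the LD matrix are sufficient: $X_g^\top e_g = n\tilde{w}$ and
$X_g^\top X_g = nR$. In practice the marginal standardized effects are
recovered from Z statistics as $\tilde{w}_j \approx Z_j / \sqrt{n_g}$ with
$n_g$ the gene's *median* cis-eQTL sample size (summary sets are
meta-analyses, so per-SNP n varies; the median is used for robustness and is
the sample size handed to every estimator). All four estimators consume only
$(\tilde{w}, R, n_g)$:

* **P+T** — LD clumping at $R_T = 0.99$ followed by p-value thresholding at
  $P_T \in \{0.001, 0.05\}$; survivors keep their marginal effect as weight.
  Retention is boundary-inclusive ($p \le P_T$), and clumping precedes
  thresholding as in the PLINK convention.
* **Summary-statistic LASSO** (lassosum-style) — minimizes
  $(1-s)\,w^\top R w + s\,w^\top w - 2\tilde{w}^\top w + 2\lambda\lVert w\rVert_1$
  by blockwise coordinate descent, where $R_s = (1-s)R + sI$ regularizes the
  reference LD. The pair $(s, \lambda)$ is tuned per gene by
  pseudovalidation, maximizing $\mathrm{pv}(w) = w^\top\tilde{w} /
  \sqrt{w^\top R w}$. The grid includes $s = 1$ (pure soft-thresholding) as a
  positive-definite fallback.
* **Dirichlet-process normal mixture** (SDPR-style) — $w_j \sim \sum_{k=0}^M
  \pi_k N(0, \sigma^2_k)$ with a point-mass null component
  ($\sigma^2_0 = 0$), truncated stick-breaking weights (default $M = 20$,
  concentration $\alpha = 1$) and an inverse-gamma base for the component
  variances. Gibbs sampling uses single-site sweeps in which the component
  assignment is drawn with $w_j$ integrated out — this accommodates the
  point-mass null exactly and has the same stationary distribution as a
  blocked update.
* **Continuous shrinkage** (PRS-CS-style) — $w_j \sim N(0,
  \tfrac{\sigma^2_\epsilon}{n}\psi_j)$ with gamma-gamma local scales
  ($\psi_j \sim \mathrm{G}(a, \delta_j)$, $\delta_j \sim \mathrm{G}(b, \phi)$,
  $a = 1$, $b = 1/2$): a sharp peak at zero shrinks noise while Cauchy-like
  tails leave strong eQTLs nearly untouched. The residual variance carries
  the scale-invariant Jeffreys prior $p(\sigma^2_\epsilon) \propto
  1/\sigma^2_\epsilon$. The global scale $\phi$ is fixed per run: $10^{-4}$
  is the real-data default, and simulation mode uses the squared causal
  proportion. Local scales are capped at $\psi_j \le 1$ so no single SNP's
  prior variance exceeds $\sigma^2_\epsilon/n$, as in reference
  continuous-shrinkage implementations.

Stage II computes, per gene and method, the summary-statistic Z test
$$Z_g = \frac{\sum_j \hat{w}_j Z_j}{\sqrt{\hat{w}^\top V \hat{w}}},$$
with $V$ the reference LD correlation matrix (correlation form) or covariance
matrix with per-SNP scales in the numerator (covariance form); the two forms
coincide when weights are on the standardized scale and all genotype scales
are one. Per-method p-values are optionally genomic-control corrected
(scaling so the median test p equals 0.5 via $\lambda_{gc} =
\mathrm{median}(z^2)/0.45494$, the $\chi^2_1$ median truncated at four
decimals) and combined as
$$p_{\mathrm{omnibus}} = \tfrac12 - \tfrac{1}{\pi}\arctan\Big(\tfrac1k
\textstyle\sum_i \tan\{(\tfrac12 - p_i)\pi\}\Big),$$
with equal weights over the available methods (the source publications do not
specify weights), methods lacking a test or a valid model excluded with $k$
reduced accordingly, and numerically stable tails ($\tan\{(\frac12-p)\pi\}
\to 1/(p\pi)$ below $10^{-15}$, and the inverse mapping below the arctan
resolution limit).

## Fitting interface

The classic modelling idiom: `grex_fit()` is the fitting function, returning
an object with `coef()` (the weight matrix), `predict()` (GReX imputation in
new samples), `print()` and `summary()` methods. `twas_scan()` runs Stage II
over a list of fitted genes; `run_stage1()`/`run_stage2()` provide the
file-level orchestration used by the `inst/cli/sumtwas` script.

```{r, eval = FALSE}
library(sumtwas)
ss    <- read_eqtl_sumstats("eqtl.tsv", "ENSG000001", list("1", 1e6, 3e6))
panel <- read_plink("ld_panel", region = list("1", 1e6, 3e6))
fit   <- grex_fit(ss, panel, seed = 1)
coef(fit)                     # SNP x method weight matrix
gwas  <- read_gwas_sumstats("gwas.tsv")
twas_scan(list(fit), gwas)    # per-method Z/p + omnibus p
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `cis_radius` | 1 Mb | cis-window half-width around the TSS |
| `clump_r2` ($R_T$) | 0.99 | LD clumping threshold, applied before *every* method |
| `block_r2` | 0.1 | maximal cross-block squared correlation |
| `P_T` | 0.001, 0.05 | the two P+T p-value thresholds |
| `s_grid`, `lambda_grid` | \{0.2, 0.5, 0.9, 1\}, 20 points on $[10^{-3}, 10^{-1}]$ | LASSO tuning grids |
| `n_components`, `concentration` | 20, 1 | mixture truncation and DP concentration |
| `a`, `b`, `phi` | 1, 0.5, $10^{-4}$ | continuous-shrinkage hyperparameters |
| `iters`, `burnin` | 1000, 200 | MCMC schedule for both samplers |
| `jitter` | $10^{-3}$ | diagonal jitter for LD factorizations, escalated ×10 up to 3 times |
| valid-model cutoff | $R^2 > 0.01$ | strict inequality, out-of-sample |
| independence cutoff | GReX $r^2 > 0.5$ | greedy pruning by ascending p |

## The synthetic-data generator

The simulation harness emulates the published protocol: 568 training and
1326 testing samples (a 30/70 split of 1894), causal proportions
$p_{causal} \in \{0.001, 0.01\}$ with the count rule $\max(1,
\mathrm{round}(p_{causal} m))$, expression heritability $h_e^2 \in \{0.01,
0.05, 0.1\}$ enforced *exactly* by rescaling the causal effects, noise
$N(0, 1 - h_e^2)$, and GWAS Z-scores drawn from their asymptotic law
$Z \sim \mathrm{MVN}(\Sigma_g w \sqrt{n_{gwas} h_p^2}, \Sigma_g)$ with
$h_p^2 = 0.025$ and $\Sigma_g$ the test-split LD.

The original study used restricted-access whole-genome-sequencing genotypes;
the generator substitutes an AR(1) latent Gaussian haplotype model
thresholded at the SNP's MAF quantile (MAF $\sim U(0.05, 0.5)$; neither the
MAF filter nor the LD of the source data is published, so these are chosen
once as typical of common-variant cis-windows). The default latent
correlation $\rho = 0.9$ gives adjacent-SNP dosage $r^2 \approx 0.4$–$0.6$,
i.e. realistic strong local LD with ~tens of effectively independent blocks
per 500 SNPs. What this generator does *not* emulate: allele-frequency-
dependent effect sizes, haplotype block boundaries with recombination
hotspots, imputation uncertainty, and cross-population LD differences — so a
green simulation suite establishes correct behaviour of the estimators under
the stated generative model, not performance on any particular cohort.

The type-I-error protocol follows the published permuted-weight null:
phenotype-free GWAS Z-scores are drawn from $\mathrm{MVN}(0, \Sigma)$ and the
trained weights are randomly permuted across SNPs before each test. Under
this construction the gene-based statistic is exactly standard normal, so
the calibration check is sharp.

## Numerical and design choices

* **Blocks**: the source work delegates block boundaries to an external tool
  for two of the methods and computes them internally for the third; here a
  single internal greedy partition (cross-block $r^2 \le 0.1$) serves all
  three, with an option to load precomputed boundaries from a BED file.
* **Coordinate descent** stops when the largest coordinate change is below
  `tol` ($10^{-4}$; tightened in tests); the objective is returned per sweep
  and is non-increasing. Warm starts run along each $\lambda$ path from
  sparse to dense at fixed $s$; at convergence this affects nothing.
* **Pseudovalidation ties** break toward larger $s$, then larger $\lambda$;
  all-zero candidates score $-\infty$; an all-zero grid yields an empty
  weight set (the gene is skipped downstream, a no-test signal rather than
  an error).
* **Clumping ties** on identical p-values break by genomic position, making
  the retained set independent of input row order.
* **Residual variance guard**: the summary-statistic residual sum of squares
  $1 - 2w^\top\tilde{w} + w^\top R w$ is clamped below at $10^{-8}$ before
  the inverse-gamma draw (it can go slightly negative when $R$ comes from a
  different sample than $\tilde{w}$).
* **Harmonization**: variants are matched by position; allele swaps flip the
  effect sign; strand-ambiguous (A/T, C/G) variants are dropped rather than
  frequency-resolved because input frequencies are not guaranteed;
  multi-allelic panel positions are dropped and counted (their treatment in
  the source work is unstated).
* **Per-gene seeding** derives each gene's RNG seed from the master seed and
  the gene identifier, so results are independent of scheduling order; both
  Gibbs samplers draw exclusively from R's RNG and are bit-reproducible.
* **Tuning scope**: the LASSO pair $(s, \lambda)$ is tuned per gene (whether
  the source work tuned per gene or globally is unstated; per-gene matches
  the per-gene independence of the rest of the pipeline).
* **Printed-prior discrepancy**: the source text prints the residual-variance
  prior as $p(\sigma^2_\epsilon) \propto \sigma^2_\epsilon$; the package
  implements the standard scale-invariant form $\propto 1/\sigma^2_\epsilon$
  (the printed form is improper in a way that breaks the conditional and is
  taken as a typo; the same text calls the prior "non-informative
  scale-invariant Jeffreys").

## Known limitations

* Only cis effects are modelled; trans-eQTL are out of scope.
* The omnibus test reports no direction of effect; consult the per-method Z
  signs.
* Cauchy combination can be slightly anti-conservative at modest significance
  levels when the combined tests are strongly dependent; tail-level
  calibration is what the test suite verifies.
* The LASSO pseudovalidation statistic rewards dense solutions when the
  number of cis-SNPs approaches the training sample size, which depresses
  that method's accuracy in such regimes (visible in the simulation suite);
  this is a property of the published tuning rule, not of the optimizer.
* No sample-level QC is performed on the LD panel; it is assumed
  ancestry-matched and pre-filtered, and cross-population weight transfer is
  out of scope.
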