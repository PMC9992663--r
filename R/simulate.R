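## Simulation harness: correlated diploid genotypes, expression from a sparse
## linear model, single-SNP eQTL summary statistics, GWAS Z-scores drawn from
## their asymptotic multivariate-normal distribution, and the evaluation
## metrics (test R-squared, power, type-I error).

#' Simulation configuration
#'
#' Defaults follow the reference simulation protocol: 568 training and 1326
#' testing samples (a 30/70 split of 1894), causal proportions 0.001 or 0.01,
#' expression heritability 0.01/0.05/0.1, and GReX-explained phenotype
#' variance `h_p2 = 0.025`. Genotypes are generated from an AR(1) latent
#' Gaussian haplotype model (`ld_rho`) thresholded at MAF drawn uniformly
#' from `maf_range` — a stand-in for the restricted-access reference
#' genotypes with controllable LD.
#'
#' @param n_train,n_test sample sizes of the training (eQTL) and testing
#'   (LD/GWAS) splits.
#' @param m_snps number of cis-SNPs.
#' @param ld_rho AR(1) latent haplotype correlation in \[0, 1).
#' @param maf_range minor-allele-frequency sampling interval.
#' @param p_causal proportion of causal cis-eQTL.
#' @param h_e2 expression variance explained by the causal eQTL.
#' @param h_p2 phenotype variance explained by GReX.
#' @param n_gwas GWAS sample size for Z-score simulation.
#' @param seed RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_train = 568L, n_test = 1326L, m_snps = 500L,
                       ld_rho = 0.9, maf_range = c(0.05, 0.5),
                       p_causal = 0.001, h_e2 = 0.1, h_p2 = 0.025,
                       n_gwas = 10000L, seed = NULL) {
  stopifnot(h_e2 >= 0, h_e2 < 1, h_p2 >= 0, h_p2 < 1,
            ld_rho >= 0, ld_rho < 1, m_snps >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 m_snps = as.integer(m_snps), ld_rho = ld_rho,
                 maf_range = maf_range, p_causal = p_causal, h_e2 = h_e2,
                 h_p2 = h_p2, n_gwas = as.integer(n_gwas), seed = seed),
            class = "sim_config")
}

#' Simulate correlated diploid genotypes
#'
#' Each haplotype is a latent AR(1) Gaussian process along the SNP index,
#' thresholded at the SNP's MAF quantile; the dosage is the sum of two
#' haplotypes. Per-SNP MAFs are drawn uniformly from `maf_range`.
#'
#' @param config a [sim_config()].
#' @return list with `train` and `test` `genotype_panel`s sharing one variant
#'   table, plus `maf` (the sampled allele frequencies).
#' @export
simulate_genotypes <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- config$m_snps
  n <- config$n_train + config$n_test
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(maf)
  rho <- config$ld_rho
  H <- matrix(0, 2L * n, m)
  H[, 1] <- stats::rnorm(2L * n)
  if (m > 1) {
    innov_sd <- sqrt(1 - rho^2)
    for (j in 2:m) H[, j] <- rho * H[, j - 1] + innov_sd * stats::rnorm(2L * n)
  }
  alleles <- sweep(H, 2, thr, "<") * 1
  dosage <- alleles[seq_len(n), , drop = FALSE] + alleles[n + seq_len(n), , drop = FALSE]
  meta <- data.frame(chrom = "1", pos = 1000000L + 1000L * seq_len(m),
                     ref = "A", alt = "G",
                     id = paste0("snp", seq_len(m)), stringsAsFactors = FALSE)
  train_idx <- seq_len(config$n_train)
  list(train = genotype_panel(dosage[train_idx, , drop = FALSE], meta,
                              paste0("TR", train_idx)),
       test = genotype_panel(dosage[-train_idx, , drop = FALSE], meta,
                             paste0("TE", seq_len(config$n_test))),
       maf = maf)
}

#' Simulate gene expression from a sparse linear genetic model
#'
#' Picks `max(1, round(p_causal * m))` causal SNPs, draws their effects from
#' N(0, 1), rescales them so the empirical variance of `X w` equals `h_e2`
#' exactly, and adds N(0, 1 - h_e2) noise. With `h_e2 = 0` the effects are
#' all zero and expression is pure noise.
#'
#' @param X standardized genotype matrix (train and test rows together).
#' @param config a [sim_config()].
#' @return list (`sim_truth`) with `causal_indices`, `w_true` (length-m
#'   standardized effects) and `expression` (per-sample, same row order
#'   as `X`).
#' @export
simulate_expression <- function(X, config) {
  m <- ncol(X)
  n <- nrow(X)
  n_causal <- max(1L, round(config$p_causal * m))
  causal <- sort(sample.int(m, n_causal))
  w <- numeric(m)
  if (config$h_e2 > 0) {
    w[causal] <- stats::rnorm(n_causal)
    g <- as.numeric(X %*% w)
    vg <- mean((g - mean(g))^2)
    if (vg > 0) w <- w * sqrt(config$h_e2 / vg)
  }
  g <- as.numeric(X %*% w)
  e <- g + stats::rnorm(n, 0, sqrt(1 - config$h_e2))
  structure(list(causal_indices = causal, w_true = w, expression = e),
            class = "sim_truth")
}

#' Single-SNP eQTL summary statistics from individual-level data
#'
#' For each SNP, runs the single-variant regression of expression on the
#' standardized genotype: marginal effect `w_j = x_j' e / n`, with the OLS
#' t-statistic treated as a normal Z and a two-sided p-value. Expression is
#' standardized internally.
#'
#' @param X standardized genotype matrix (training samples).
#' @param e expression vector.
#' @param gene_id gene identifier for the output object.
#' @param variant_meta optional variant table (chrom, pos, ref, alt).
#' @return an `eqtl_sumstats` object; `beta_marginal` holds the exact
#'   marginal effect on the standardized scale.
#' @export
eqtl_sumstats_from_individual <- function(X, e, gene_id = "gene", variant_meta = NULL) {
  n <- nrow(X)
  m <- ncol(X)
  stopifnot(length(e) == n, n >= 3)
  e_std <- (e - mean(e)) / sqrt(mean((e - mean(e))^2))
  beta <- as.numeric(crossprod(X, e_std)) / n
  r2 <- pmin(beta^2, 1 - 1e-12)
  z <- beta * sqrt((n - 2) / (1 - r2))
  p <- pmax(z_to_p(z), .Machine$double.xmin)
  if (is.null(variant_meta)) {
    variant_meta <- data.frame(chrom = "1", pos = 1000000L + 1000L * seq_len(m),
                               ref = "A", alt = "G", stringsAsFactors = FALSE)
  }
  records <- data.frame(chrom = as.character(variant_meta$chrom),
                        pos = as.integer(variant_meta$pos),
                        ref = as.character(variant_meta$ref),
                        alt = as.character(variant_meta$alt),
                        z = z, p = p, n = rep(n, m),
                        beta_marginal = beta, stringsAsFactors = FALSE)
  new_eqtl_sumstats(gene_id, records, as.integer(n))
}

#' Simulate GWAS Z-scores given true eQTL effects
#'
#' Draws `Z ~ MVN(Sigma w sqrt(n_gwas * h_p2), Sigma)`, the asymptotic
#' distribution of single-SNP GWAS Z statistics when the phenotype carries a
#' GReX signal with variance share `h_p2`; `Sigma` is the test-sample LD
#' correlation matrix.
#'
#' @param w_true true standardized eQTL effect sizes.
#' @param Sigma_g test-sample LD correlation matrix (or `ld_structure`).
#' @param config a [sim_config()] (supplies `n_gwas` and `h_p2`).
#' @param n_reps number of independent Z-score vectors.
#' @return m x n_reps matrix of GWAS Z-scores (a vector when `n_reps = 1`).
#' @export
simulate_gwas_z <- function(w_true, Sigma_g, config, n_reps = 1L) {
  if (inherits(Sigma_g, "ld_structure")) Sigma_g <- Sigma_g$R
  m <- length(w_true)
  stopifnot(nrow(Sigma_g) == m)
  mu <- as.numeric(Sigma_g %*% w_true) * sqrt(config$n_gwas * config$h_p2)
  U <- chol_jitter(Sigma_g)
  Z <- mu + crossprod(U, matrix(stats::rnorm(m * n_reps), m, n_reps))
  if (n_reps == 1L) as.numeric(Z) else Z
}

#' Imputation accuracy: squared Pearson correlation
#'
#' @param grex imputed GReX vector.
#' @param expression observed/simulated expression vector (same length >= 3).
#' @return squared Pearson correlation; 0 (with attribute `constant = TRUE`)
#'   when either vector is constant.
#' @export
test_r2 <- function(grex, expression) {
  if (length(grex) != length(expression)) stop("length mismatch")
  stopifnot(length(grex) >= 3)
  if (stats::sd(grex) == 0 || stats::sd(expression) == 0) {
    return(structure(0, constant = TRUE))
  }
  stats::cor(grex, expression)^2
}

#' Empirical power / type-I error
#'
#' @param p_values vector of TWAS p-values across repeated simulations.
#' @param threshold significance threshold in (0, 1), e.g.
#'   [bonferroni()]`(0.05, 20000)`.
#' @return the fraction of p-values strictly below `threshold` (NAs count as
#'   non-significant).
#' @export
power_and_type1 <- function(p_values, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  mean(!is.na(p_values) & p_values < threshold)
}

#' Permuted-weight null TWAS p-values
#'
#' The type-I-error protocol: under the null the GWAS Z-scores are drawn from
#' MVN(0, Sigma) and the trained eQTL weights are randomly permuted across
#' SNPs before each test, breaking any weight/LD alignment. Returns the
#' two-sided p-values of the gene-based Z statistic for `n_tests` independent
#' null replicates.
#'
#' @param weights numeric weight vector (length m, zeros allowed).
#' @param Sigma LD correlation matrix of the m SNPs (or `ld_structure`).
#' @param n_tests number of null tests.
#' @return numeric vector of `n_tests` p-values (NA where the permuted
#'   quadratic form degenerates, which cannot happen for a non-zero weight
#'   vector and positive-definite Sigma).
#' @export
permuted_null_pvalues <- function(weights, Sigma, n_tests) {
  if (inherits(Sigma, "ld_structure")) Sigma <- Sigma$R
  m <- length(weights)
  stopifnot(nrow(Sigma) == m, any(weights != 0))
  U <- chol_jitter(Sigma)
  Z <- crossprod(U, matrix(stats::rnorm(m * n_tests), m, n_tests))
  W <- vapply(seq_len(n_tests), function(i) weights[sample.int(m)], numeric(m))
  num <- colSums(W * Z)
  den2 <- colSums(W * (Sigma %*% W))
  ifelse(den2 > 1e-12, z_to_p(num / sqrt(den2)), NA_real_)
}

#' One end-to-end simulation replicate
#'
#' Simulates genotypes and expression, derives training-sample eQTL summary
#' statistics, trains the requested Stage-I methods, computes test R-squared
#' per method, and runs the Stage-II association test against `n_gwas_reps`
#' simulated GWAS Z-score vectors.
#'
#' @param config a [sim_config()].
#' @param methods Stage-I methods to train.
#' @param n_gwas_reps GWAS Z-score draws per trained replicate.
#' @param seed RNG seed (fully determines the replicate).
#' @param sdpr,prscs,lassosum method configurations; by default `prscs` uses
#'   `phi = p_causal^2` as in the simulation protocol.
#' @return list with `p` (n_gwas_reps x methods matrix of TWAS p-values),
#'   `p_acat` (omnibus p-value per GWAS draw), `r2` (named per-method test
#'   R-squared), `truth` (the `sim_truth`) and `fit` (the `grex_fit`).
#' @export
simulate_twas_replicate <- function(config, methods = ALL_METHODS, n_gwas_reps = 10L,
                                    seed = 1L,
                                    sdpr = sdpr_config(),
                                    prscs = prscs_config(phi = config$p_causal^2),
                                    lassosum = lassosum_config()) {
  cfg <- config
  cfg$seed <- derive_seed(seed, "genotypes")
  geno <- simulate_genotypes(cfg)
  std_all <- standardize(rbind(geno$train$dosage, geno$test$dosage))
  if (length(std_all$kept) < ncol(geno$train$dosage)) {
    # keep the SNP sets of all three matrices aligned
    for (part in c("train", "test")) {
      geno[[part]]$dosage <- geno[[part]]$dosage[, std_all$kept, drop = FALSE]
      geno[[part]]$variant_meta <- geno[[part]]$variant_meta[std_all$kept, , drop = FALSE]
    }
  }
  set.seed(derive_seed(seed, "expression"))
  truth <- simulate_expression(std_all$X, config)
  n_train <- nrow(geno$train$dosage)
  train_rows <- seq_len(n_train)

  std_train <- standardize(geno$train)
  e_train <- truth$expression[train_rows]
  ss <- eqtl_sumstats_from_individual(std_train$X, e_train, "simgene", std_train$meta)

  fit <- grex_fit(ss, geno$train, methods = methods, sdpr = sdpr, prscs = prscs,
                  lassosum = lassosum, seed = derive_seed(seed, "stage1"))

  std_test <- standardize(geno$test)
  e_test <- truth$expression[-train_rows]
  grex <- predict(fit, std_test$X, std_test$meta)
  r2 <- apply(grex, 2, function(g) {
    if (stats::sd(g) == 0) 0 else as.numeric(test_r2(g, e_test))
  })

  Sigma <- compute_ld(std_test$X)$R
  set.seed(derive_seed(seed, "gwas"))
  Zmat <- simulate_gwas_z(truth$w_true, Sigma, config, n_reps = n_gwas_reps)
  Zmat <- matrix(Zmat, ncol = n_gwas_reps)

  test_keys <- variant_key(std_test$meta$chrom, std_test$meta$pos,
                           std_test$meta$ref, std_test$meta$alt)
  fit_keys <- variant_key(fit$variants$chrom, fit$variants$pos,
                          fit$variants$ref, fit$variants$alt)
  cols <- match(fit_keys, test_keys)
  W <- coef(fit)
  pmat <- matrix(NA_real_, n_gwas_reps, length(fit$weights),
                 dimnames = list(NULL, names(fit$weights)))
  p_acat <- rep(NA_real_, n_gwas_reps)
  for (r in seq_len(n_gwas_reps)) {
    zr <- Zmat[cols, r]
    for (m in colnames(W)) {
      use <- which(W[, m] != 0 & !is.na(zr))
      if (length(use) == 0) next
      res <- twas_z(W[use, m], zr[use], Sigma[cols[use], cols[use], drop = FALSE],
                    form = "fusion")
      if (!is.null(res)) pmat[r, m] <- res$p
    }
    p_acat[r] <- if (all(!is.finite(pmat[r, ]))) NA_real_ else acat_o(pmat[r, ])
  }
  list(p = pmat, p_acat = p_acat, r2 = r2, truth = truth, fit = fit)
}

#' Power study over repeated replicates of one scenario
#'
#' Repeats [simulate_twas_replicate()] `n_expr_reps` times (each with
#' `n_gwas_reps` GWAS draws) and tabulates empirical power at `threshold` for
#' every Stage-I method and the omnibus test.
#'
#' @param config a [sim_config()].
#' @param n_expr_reps expression/training replicates.
#' @param n_gwas_reps GWAS Z-score draws per training replicate.
#' @param threshold significance threshold (default the 20K-gene level
#'   2.5e-6).
#' @param seed master seed.
#' @param methods Stage-I methods.
#' @return list with `power` (named vector, methods plus `"ACAT"`), `p`
#'   (stacked p-value matrix), `p_acat`, `r2` (replicates x methods), and
#'   `n_tests`.
#' @export
run_power_scenario <- function(config, n_expr_reps = 20L, n_gwas_reps = 10L,
                               threshold = bonferroni(0.05, 20000), seed = 1L,
                               methods = ALL_METHODS) {
  p_all <- NULL
  acat_all <- numeric(0)
  r2_all <- NULL
  for (r in seq_len(n_expr_reps)) {
    rep_res <- simulate_twas_replicate(config, methods = methods,
                                       n_gwas_reps = n_gwas_reps,
                                       seed = derive_seed(seed, paste0("rep", r)))
    p_all <- rbind(p_all, rep_res$p)
    acat_all <- c(acat_all, rep_res$p_acat)
    r2_all <- rbind(r2_all, rep_res$r2)
  }
  power <- c(apply(p_all, 2, power_and_type1, threshold = threshold),
             ACAT = power_and_type1(acat_all, threshold))
  list(power = power, p = p_all, p_acat = acat_all, r2 = r2_all,
       n_tests = length(acat_all))
}
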