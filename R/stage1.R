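## Stage-I trainers: each takes harmonized per-gene eQTL summary statistics
## plus an LD reference and returns an `eqtl_weights` object on the
## standardized-genotype, standardized-expression scale.

weights_from_vector <- function(gene_id, method, records, w, drop_zero = TRUE) {
  keep <- if (drop_zero) which(w != 0) else seq_along(w)
  entries <- data.frame(chrom = records$chrom[keep], pos = records$pos[keep],
                        ref = records$ref[keep], alt = records$alt[keep],
                        weight = w[keep], stringsAsFactors = FALSE)
  new_eqtl_weights(gene_id, method, entries)
}

#' P+T configuration
#'
#' @param p_threshold marginal p-value retention threshold P_T (a SNP is kept
#'   when `p <= p_threshold`); the canonical settings are 0.001 and 0.05.
#' @param r2_threshold clumping threshold R_T (default 0.99).
#' @return a list of class `pt_config`.
#' @export
pt_config <- function(p_threshold = 0.001, r2_threshold = 0.99) {
  stopifnot(p_threshold > 0, p_threshold <= 1, r2_threshold > 0, r2_threshold <= 1)
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold),
            class = "pt_config")
}

#' Clumping + thresholding (P+T) weights
#'
#' LD-clumps the gene's cis-SNPs at `R_T`, then keeps clump index SNPs with
#' marginal p-value at most `P_T`; surviving SNPs get their marginal
#' standardized effect size as weight (no re-estimation). An empty survivor
#' set is a valid result (the gene is skipped downstream).
#'
#' @param sumstats harmonized `eqtl_sumstats`.
#' @param ld an `ld_structure` (or correlation matrix) over the same SNPs.
#' @param config a [pt_config()].
#' @return an `eqtl_weights` object (method `PT_<threshold>`).
#' @export
fit_pt <- function(sumstats, ld, config = pt_config()) {
  rec <- sumstats$records
  kept <- ld_clump(sumstats, ld, config$r2_threshold)
  kept <- kept[rec$p[kept] <= config$p_threshold]
  w <- numeric(nrow(rec))
  w[kept] <- rec$beta_marginal[kept]
  method <- sprintf("PT_%s", sub("^0\\.", "", format(config$p_threshold, scientific = FALSE)))
  weights_from_vector(sumstats$gene_id, method, rec, w)
}

#' lassosum configuration
#'
#' @param s_grid LD shrinkage grid; `s = 1` is the LD-free (pure
#'   soft-thresholding) limit, kept as a positive-definite fallback.
#' @param lambda_grid L1 penalty grid (default 20 values log-spaced on
#'   \[1e-3, 1e-1\]).
#' @param max_iter,tol coordinate-descent stopping rule (max absolute
#'   coordinate change).
#' @return a list of class `lassosum_config`.
#' @export
lassosum_config <- function(s_grid = c(0.2, 0.5, 0.9, 1),
                            lambda_grid = exp(seq(log(1e-3), log(1e-1), length.out = 20)),
                            max_iter = 500L, tol = 1e-4) {
  stopifnot(length(s_grid) > 0, all(s_grid > 0 & s_grid <= 1),
            length(lambda_grid) > 0, all(lambda_grid > 0))
  structure(list(s_grid = s_grid, lambda_grid = lambda_grid,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "lassosum_config")
}

#' Single lassosum solve at fixed (s, lambda)
#'
#' Minimizes `(1-s) w'Rw + s w'w - 2 beta'w + 2 lambda ||w||_1` by blockwise
#' cyclic coordinate descent. With unit-diagonal R the coordinate update is
#' `w_j <- soft(beta_j - (1-s) * sum_{k!=j} R_jk w_k, lambda)`.
#'
#' @param betas marginal standardized effects (w-tilde).
#' @param ld `ld_structure` (blocks are honoured) or correlation matrix.
#' @param s shrinkage weight in (0, 1\].
#' @param lambda L1 penalty.
#' @param max_iter,tol stopping rule.
#' @param w_init optional warm start.
#' @return list with `w`, `converged`, `iterations`, and the per-sweep
#'   `objective` values (non-increasing).
#' @export
fit_lassosum_single <- function(betas, ld, s, lambda, max_iter = 500L, tol = 1e-4,
                                w_init = NULL) {
  R <- if (inherits(ld, "ld_structure")) ld$R else ld
  blocks <- if (inherits(ld, "ld_structure")) ld$blocks else list(seq_len(nrow(R)))
  if (is.null(w_init)) w_init <- numeric(length(betas))
  res <- lassosum_cd_cpp(as.numeric(betas), R, blocks, s, lambda,
                         as.integer(max_iter), tol, as.numeric(w_init))
  if (!res$converged) {
    warning(sprintf("lassosum coordinate descent did not converge (s=%g, lambda=%g)",
                    s, lambda))
  }
  res$w <- as.numeric(res$w)
  res
}

#' Pseudovalidation score and candidate selection
#'
#' Scores each candidate weight vector by `pv(w) = w'beta / sqrt(w' R w)` and
#' returns the maximizer; all-zero candidates score -Inf. Ties break toward
#' larger `s`, then larger `lambda`.
#'
#' @param candidates list of candidates, each a list with elements `w`, `s`,
#'   `lambda`.
#' @param betas marginal standardized effects.
#' @param ld reference LD (`ld_structure` or matrix).
#' @return the winning candidate augmented with its `pv` score, or `NULL`
#'   when every candidate is all-zero.
#' @export
pseudovalidate <- function(candidates, betas, ld) {
  R <- if (inherits(ld, "ld_structure")) ld$R else ld
  stopifnot(length(candidates) >= 1)
  score <- vapply(candidates, function(cand) {
    w <- cand$w
    if (all(w == 0)) return(-Inf)
    denom <- sqrt(max(as.numeric(crossprod(w, R %*% w)), 1e-300))
    sum(w * betas) / denom
  }, numeric(1))
  if (all(!is.finite(score))) return(NULL)
  s_vals <- vapply(candidates, `[[`, numeric(1), "s")
  lam_vals <- vapply(candidates, `[[`, numeric(1), "lambda")
  best <- order(-score, -s_vals, -lam_vals)[1]
  out <- candidates[[best]]
  out$pv <- score[best]
  out
}

#' Summary-statistic LASSO (lassosum-style) weights
#'
#' Solves the shrunken-LD L1 problem over a grid of (s, lambda) with warm
#' starts along each lambda path, then picks the pseudovalidation winner.
#'
#' @param sumstats harmonized `eqtl_sumstats`.
#' @param ld `ld_structure` over the same SNPs.
#' @param config a [lassosum_config()].
#' @return an `eqtl_weights` object (method `LASSOSUM`) with attributes
#'   `s` and `lambda` recording the tuned pair; empty when every candidate
#'   is all-zero.
#' @export
fit_lassosum <- function(sumstats, ld, config = lassosum_config()) {
  rec <- sumstats$records
  betas <- rec$beta_marginal
  candidates <- list()
  lambdas <- sort(config$lambda_grid, decreasing = TRUE) # warm starts dense -> sparse? high lambda first
  for (s in config$s_grid) {
    w <- numeric(length(betas))
    for (lam in lambdas) {
      fit <- fit_lassosum_single(betas, ld, s, lam, config$max_iter, config$tol,
                                 w_init = w)
      w <- fit$w
      candidates[[length(candidates) + 1L]] <- list(w = w, s = s, lambda = lam)
    }
  }
  best <- pseudovalidate(candidates, betas, ld)
  if (is.null(best)) {
    return(weights_from_vector(sumstats$gene_id, "LASSOSUM", rec, numeric(nrow(rec))))
  }
  out <- weights_from_vector(sumstats$gene_id, "LASSOSUM", rec, best$w)
  attr(out, "s") <- best$s
  attr(out, "lambda") <- best$lambda
  attr(out, "pv") <- best$pv
  out
}

#' Dirichlet-process mixture (SDPR-style) configuration
#'
#' @param n_components truncation level M of the stick-breaking mixture
#'   (plus a point-mass null component).
#' @param concentration Dirichlet-process concentration alpha.
#' @param base_shape,base_rate inverse-gamma base-distribution hyperparameters
#'   for the component variances.
#' @param iters,burnin,thin MCMC schedule.
#' @param jitter diagonal jitter for LD block factorizations.
#' @return a list of class `sdpr_config`.
#' @export
sdpr_config <- function(n_components = 20L, concentration = 1,
                        base_shape = 0.1, base_rate = 0.1,
                        iters = 1000L, burnin = 200L, thin = 1L, jitter = 1e-3) {
  stopifnot(n_components >= 2, burnin < iters)
  structure(list(n_components = as.integer(n_components), concentration = concentration,
                 base_shape = base_shape, base_rate = base_rate,
                 iters = as.integer(iters), burnin = as.integer(burnin),
                 thin = as.integer(thin), jitter = jitter),
            class = "sdpr_config")
}

#' Dirichlet-process regression weights from summary statistics
#'
#' Fits the truncated stick-breaking normal-mixture model with a point-mass
#' null component by Gibbs sampling, using only the summary sufficient
#' statistics (n * w-tilde, n * R). Returns posterior-mean weights. Runs are
#' bit-reproducible for a fixed `seed`.
#'
#' @param sumstats harmonized `eqtl_sumstats` (or a numeric vector of
#'   marginal standardized effects).
#' @param ld `ld_structure` with blocks over the same SNPs.
#' @param config an [sdpr_config()].
#' @param n sample size; defaults to the gene's `n_median`.
#' @param seed RNG seed.
#' @param fixed_sigma2,fixed_sigma2_eps internal oracle hooks: a positive
#'   `fixed_sigma2` pins every SNP to one normal component of that variance
#'   (conjugate closed-form check); a positive `fixed_sigma2_eps` freezes the
#'   residual variance.
#' @return an `eqtl_weights` object (method `SDPR`) with attributes
#'   `pi_mean` (posterior mixture proportions) and `counts` (last-iteration
#'   component occupancy).
#' @export
fit_sdpr <- function(sumstats, ld, config = sdpr_config(), n = NULL, seed = NULL,
                     fixed_sigma2 = -1, fixed_sigma2_eps = -1) {
  if (inherits(sumstats, "eqtl_sumstats")) {
    rec <- sumstats$records
    betas <- rec$beta_marginal
    if (is.null(n)) n <- sumstats$n_median
    gene_id <- sumstats$gene_id
  } else {
    betas <- as.numeric(sumstats)
    rec <- data.frame(chrom = "0", pos = seq_along(betas), ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
    gene_id <- "gene"
  }
  stopifnot(!is.null(n), n >= 2)
  R <- if (inherits(ld, "ld_structure")) ld$R else ld
  blocks <- if (inherits(ld, "ld_structure")) ld$blocks else list(seq_len(nrow(R)))
  if (!is.null(seed)) set.seed(seed)
  res <- sdpr_gibbs_cpp(betas, n, R, blocks, config$n_components,
                        config$concentration, config$base_shape, config$base_rate,
                        1e-3, 1e-3, config$iters, config$burnin, config$thin,
                        fixed_sigma2, fixed_sigma2_eps)
  out <- weights_from_vector(gene_id, "SDPR", rec, as.numeric(res$w_mean))
  attr(out, "pi_mean") <- as.numeric(res$pi_mean)
  attr(out, "counts") <- as.integer(res$counts)
  attr(out, "w_full") <- as.numeric(res$w_mean)
  out
}

#' Continuous-shrinkage (PRS-CS-style) configuration
#'
#' @param a,b gamma-gamma local-scale hyperparameters (defaults 1 and 1/2 give
#'   a prior with a sharp peak at zero and Cauchy-like tails).
#' @param phi global shrinkage parameter; 1e-4 is the real-data default, and
#'   simulation studies set it to the squared causal proportion.
#' @param iters,burnin,thin MCMC schedule.
#' @param jitter diagonal jitter for LD block factorizations.
#' @return a list of class `prscs_config`.
#' @export
prscs_config <- function(a = 1, b = 0.5, phi = 1e-4,
                         iters = 1000L, burnin = 200L, thin = 1L, jitter = 1e-3) {
  stopifnot(a > 0, b > 0, phi > 0, burnin < iters)
  structure(list(a = a, b = b, phi = phi, iters = as.integer(iters),
                 burnin = as.integer(burnin), thin = as.integer(thin), jitter = jitter),
            class = "prscs_config")
}

#' Continuous-shrinkage regression weights from summary statistics
#'
#' Gibbs sampler for the gamma-gamma continuous-shrinkage prior: per-block
#' multivariate-normal draws of the effect vector, generalized
#' inverse-Gaussian draws of the local scales, gamma draws of their rates,
#' and an inverse-gamma draw of the residual variance under the
#' scale-invariant Jeffreys prior. Returns posterior-mean weights;
#' bit-reproducible for a fixed `seed`.
#'
#' @inheritParams fit_sdpr
#' @param config a [prscs_config()].
#' @param psi_fixed internal oracle hook: a length-m positive vector freezes
#'   the local scales, making the posterior mean the ridge solution
#'   `(R + Psi^-1)^-1 w-tilde` with `Psi = diag(psi)`.
#' @return an `eqtl_weights` object (method `PRSCS`) with attribute
#'   `psi_mean`.
#' @export
fit_prscs <- function(sumstats, ld, config = prscs_config(), n = NULL, seed = NULL,
                      psi_fixed = numeric(0)) {
  if (inherits(sumstats, "eqtl_sumstats")) {
    rec <- sumstats$records
    betas <- rec$beta_marginal
    if (is.null(n)) n <- sumstats$n_median
    gene_id <- sumstats$gene_id
  } else {
    betas <- as.numeric(sumstats)
    rec <- data.frame(chrom = "0", pos = seq_along(betas), ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
    gene_id <- "gene"
  }
  stopifnot(!is.null(n), n >= 2)
  R <- if (inherits(ld, "ld_structure")) ld$R else ld
  blocks <- if (inherits(ld, "ld_structure")) ld$blocks else list(seq_len(nrow(R)))
  if (!is.null(seed)) set.seed(seed)
  res <- prscs_gibbs_cpp(betas, n, R, blocks, config$a, config$b, config$phi,
                         config$iters, config$burnin, config$thin, config$jitter,
                         as.numeric(psi_fixed))
  out <- weights_from_vector(gene_id, "PRSCS", rec, as.numeric(res$w_mean))
  attr(out, "psi_mean") <- as.numeric(res$psi_mean)
  attr(out, "w_full") <- as.numeric(res$w_mean)
  out
}
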