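## Stage-II TWAS: GReX imputation, gene-based Z tests on GWAS summary
## statistics, genomic control, Cauchy-combination omnibus p-values, and
## result filtering.

#' Impute genetically regulated expression (GReX)
#'
#' `GReX = X_new %*% w` over the intersection of the weight variants and the
#' new genotype matrix's variants; variants without a weight contribute 0.
#'
#' @param X_new standardized genotype matrix for the target samples.
#' @param weights an `eqtl_weights` object, or a named numeric vector whose
#'   names are variant keys `chrom:pos:ref:alt`.
#' @param variant_meta variant table (chrom, pos, ref, alt) describing the
#'   columns of `X_new`.
#' @return numeric vector of per-sample GReX values, or `NULL` when the
#'   variant intersection is empty (empty-gene signal).
#' @export
impute_grex <- function(X_new, weights, variant_meta) {
  keys <- variant_key(variant_meta$chrom, variant_meta$pos,
                      variant_meta$ref, variant_meta$alt)
  if (inherits(weights, "eqtl_weights")) {
    e <- weights$entries
    wvec <- stats::setNames(e$weight, variant_key(e$chrom, e$pos, e$ref, e$alt))
  } else {
    wvec <- weights
  }
  idx <- match(names(wvec), keys)
  hit <- !is.na(idx)
  if (!any(hit)) return(NULL)
  as.numeric(X_new[, idx[hit], drop = FALSE] %*% wvec[hit])
}

#' Gene-based TWAS Z statistic from GWAS summary statistics
#'
#' Computes `Z_g = sum_j w_j z_j / sqrt(w' V w)` (correlation-matrix form) or
#' `Z_g = sum_j w_j sigma_j z_j / sqrt(w' V w)` (covariance-matrix form),
#' where V is the reference LD correlation (resp. covariance) matrix of the J
#' test SNPs that carry both a weight and a GWAS Z-score. With standardized
#' weights and unit genotype standard deviations the two forms coincide.
#'
#' @param weights numeric vector of eQTL weights over the J test SNPs.
#' @param z numeric vector of GWAS Z-scores for the same SNPs.
#' @param V LD correlation matrix (form "fusion") or covariance matrix
#'   (form "spredixcan") over the same SNPs.
#' @param form `"fusion"` or `"spredixcan"`.
#' @param snp_sd per-SNP genotype standard deviations (required for
#'   `"spredixcan"`; with the covariance V the numerator uses `w_j sigma_j z_j`).
#' @return list with `z` (Z_g), `p` (two-sided normal p), `n_snps`; or `NULL`
#'   (no-test signal) when J = 0 or the denominator `w'Vw` is <= 1e-12.
#' @export
twas_z <- function(weights, z, V, form = c("fusion", "spredixcan"), snp_sd = NULL) {
  form <- match.arg(form)
  J <- length(weights)
  if (J == 0) return(NULL)
  stopifnot(length(z) == J, nrow(V) == J, ncol(V) == J)
  denom2 <- as.numeric(crossprod(weights, V %*% weights))
  if (denom2 <= 1e-12) return(NULL)
  num <- if (form == "fusion") {
    sum(weights * z)
  } else {
    if (is.null(snp_sd)) stop("snp_sd is required for the covariance (spredixcan) form")
    sum(weights * snp_sd * z)
  }
  zg <- num / sqrt(denom2)
  list(z = zg, p = z_to_p(zg), n_snps = J)
}

#' Genomic control across genes
#'
#' Rescales a set of gene-level Z statistics so that the median test p-value
#' equals 0.5: `lambda_gc = median(z^2) / 0.45494` (the chi-square(1) median,
#' truncated at 4 decimals), adjusted `z = z / sqrt(lambda_gc)`. With fewer
#' than 10 genes no adjustment is made (`lambda_gc = 1`, with a warning).
#'
#' @param z_values numeric vector of per-gene Z statistics (NAs tolerated and
#'   passed through).
#' @return list with `z` (adjusted Z), `p` (adjusted two-sided p-values) and
#'   `lambda_gc`.
#' @export
genomic_control <- function(z_values) {
  ok <- !is.na(z_values)
  if (sum(ok) < 10) {
    warning("fewer than 10 genes: genomic control skipped (lambda_gc = 1)")
    return(list(z = z_values, p = z_to_p(z_values), lambda_gc = 1))
  }
  lambda_gc <- stats::median(z_values[ok]^2) / 0.45494
  z_adj <- z_values / sqrt(lambda_gc)
  list(z = z_adj, p = z_to_p(z_adj), lambda_gc = lambda_gc)
}

#' Cauchy-combination (ACAT) omnibus p-value
#'
#' `T = mean(tan((0.5 - p) * pi))` over the supplied p-values (optionally
#' weighted), returned as `0.5 - atan(T) / pi`. P-values are clipped into
#' `[1e-15, 1 - 1e-15]`; below 1e-15 the numerically stable tail
#' `tan((0.5 - p) pi) ~ 1 / (p pi)` is used. Robust to dependence among the
#' combined tests in the tail.
#'
#' @param p_values numeric vector of p-values in (0, 1); NAs are dropped.
#' @param weights optional non-negative weights (default equal); normalized
#'   to sum to 1.
#' @return the omnibus p-value, or `NULL` (no-test signal) when no finite
#'   p-value remains.
#' @export
acat_o <- function(p_values, weights = NULL) {
  keep <- is.finite(p_values)
  p <- p_values[keep]
  if (length(p) == 0) return(NULL)
  if (is.null(weights)) {
    wts <- rep(1 / length(p), length(p))
  } else {
    wts <- weights[keep]
    stopifnot(all(wts >= 0), sum(wts) > 0)
    wts <- wts / sum(wts)
  }
  small <- p < 1e-15
  p_clip <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  term <- ifelse(small, 1 / (p * pi), tan((0.5 - p_clip) * pi))
  T_stat <- sum(wts * term)
  if (T_stat > 1e15) {
    # atan(T) - pi/2 underflows; use the Cauchy tail 1/(T*pi) directly
    1 / (T_stat * pi)
  } else {
    0.5 - atan(T_stat) / pi
  }
}

#' Valid-model filter
#'
#' A trained imputation model is "valid" when its out-of-sample R-squared is
#' strictly greater than 0.01; only genes with at least one valid model enter
#' the omnibus combination.
#'
#' @param test_r2 numeric vector (or matrix, genes x methods) of test
#'   R-squared values.
#' @param cutoff validity cutoff (default 0.01, strict inequality).
#' @return logical of the same shape: `test_r2 > cutoff`.
#' @export
filter_valid <- function(test_r2, cutoff = 0.01) {
  test_r2 > cutoff
}

#' Prune to independently significant genes
#'
#' Greedy by ascending TWAS p-value: keep the gene, then drop every remaining
#' gene whose squared Pearson correlation of predicted GReX with a kept gene
#' exceeds `r2_cut`.
#'
#' @param grex_matrix samples x genes matrix of predicted GReX.
#' @param p_values per-gene TWAS p-values (columns of `grex_matrix`).
#' @param r2_cut squared-correlation cutoff (default 0.5).
#' @return integer vector of kept gene (column) indices, ascending.
#' @export
prune_independent <- function(grex_matrix, p_values, r2_cut = 0.5) {
  G <- ncol(grex_matrix)
  stopifnot(length(p_values) == G)
  if (G == 0) return(integer(0))
  ord <- order(p_values)
  alive <- rep(TRUE, G)
  kept <- logical(G)
  for (g in ord) {
    if (!alive[g]) next
    kept[g] <- TRUE
    alive[g] <- FALSE
    for (h in which(alive)) {
      r <- suppressWarnings(stats::cor(grex_matrix[, g], grex_matrix[, h]))
      if (!is.na(r) && r^2 > r2_cut) alive[h] <- FALSE
    }
  }
  which(kept)
}
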