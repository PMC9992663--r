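## The central model object: per-gene GReX imputation models trained from
## summary-level eQTL statistics plus an LD reference panel.

ALL_METHODS <- c("PT_001", "PT_05", "LASSOSUM", "SDPR", "PRSCS")

#' Train GReX imputation models for one gene
#'
#' Fits the selected summary-statistic estimators for a single gene:
#' harmonizes the eQTL summary statistics to the reference panel, LD-clumps
#' the cis-SNPs (applied to every method, with the clumping threshold of
#' 0.99), partitions the remaining SNPs into approximately independent LD
#' blocks, and trains each requested method on the clumped SNP set.
#'
#' @param sumstats an `eqtl_sumstats` object (see [read_eqtl_sumstats()]).
#' @param panel a `genotype_panel` LD reference (see [read_plink()]), assumed
#'   ancestry-matched and pre-filtered.
#' @param methods subset of `c("PT_001", "PT_05", "LASSOSUM", "SDPR", "PRSCS")`.
#' @param clump_r2 LD clumping threshold R_T (default 0.99).
#' @param block_r2 cross-block squared-correlation bound (default 0.1).
#' @param lassosum,sdpr,prscs per-method configuration objects.
#' @param seed RNG seed for the Gibbs samplers; per-method seeds are derived
#'   deterministically from it and the gene id.
#' @param blocks optional precomputed block index list (e.g. from
#'   [read_ld_blocks()]); by default blocks are partitioned internally.
#' @return an object of class `grex_fit` with components `gene_id`,
#'   `weights` (named list of `eqtl_weights` per method), `variants` (the
#'   harmonized, clumped variant table), `snp_sd` (reference-panel dosage
#'   standard deviations), `ld` (the `ld_structure` used), `n_median`,
#'   `harmonization` (drop/flip report) and `diagnostics`.
#'   Methods: [coef.grex_fit()], [predict.grex_fit()], `print`, `summary`.
#' @export
grex_fit <- function(sumstats, panel, methods = ALL_METHODS,
                     clump_r2 = 0.99, block_r2 = 0.1,
                     lassosum = lassosum_config(), sdpr = sdpr_config(),
                     prscs = prscs_config(), seed = NULL, blocks = NULL) {
  stopifnot(inherits(sumstats, "eqtl_sumstats"), inherits(panel, "genotype_panel"))
  methods <- match.arg(methods, ALL_METHODS, several.ok = TRUE)
  if (is.null(seed)) seed <- 1L

  std <- standardize(panel)
  harm <- harmonize(sumstats, std$meta)
  ss <- harm$sumstats
  if (nrow(ss$records) == 0) {
    out <- structure(list(gene_id = sumstats$gene_id, weights = list(),
                          variants = ss$records, snp_sd = numeric(0), ld = NULL,
                          n_median = sumstats$n_median, harmonization = harm$report,
                          diagnostics = list(empty = TRUE)),
                     class = "grex_fit")
    return(out)
  }
  # keep panel-order so LD is contiguous along the genome
  ord <- order(ss$records$panel_index)
  ss$records <- ss$records[ord, , drop = FALSE]
  cols <- ss$records$panel_index
  X <- std$X[, cols, drop = FALSE]
  snp_sd <- std$sd[cols]

  # one clumping pass shared by all methods
  R_full <- compute_ld(X)
  keep <- ld_clump(ss, R_full, clump_r2)
  ss$records <- ss$records[keep, , drop = FALSE]
  X <- X[, keep, drop = FALSE]
  snp_sd <- snp_sd[keep]
  ld <- compute_ld(X)
  ld$blocks <- if (is.null(blocks)) partition_blocks(ld, block_r2) else blocks

  weights <- list()
  diagnostics <- list(n_snps = nrow(ss$records), n_blocks = length(ld$blocks))
  for (m in methods) {
    weights[[m]] <- switch(
      m,
      PT_001 = fit_pt(ss, ld, pt_config(0.001, clump_r2)),
      PT_05 = fit_pt(ss, ld, pt_config(0.05, clump_r2)),
      LASSOSUM = fit_lassosum(ss, ld, lassosum),
      SDPR = fit_sdpr(ss, ld, sdpr, seed = derive_seed(seed, paste0(ss$gene_id, "/SDPR"))),
      PRSCS = fit_prscs(ss, ld, prscs, seed = derive_seed(seed, paste0(ss$gene_id, "/PRSCS")))
    )
  }
  structure(list(gene_id = sumstats$gene_id, weights = weights,
                 variants = ss$records, snp_sd = snp_sd, ld = ld,
                 n_median = ss$n_median, harmonization = harm$report,
                 diagnostics = diagnostics),
            class = "grex_fit")
}

#' @export
print.grex_fit <- function(x, ...) {
  cat(sprintf("GReX imputation models for gene %s\n", x$gene_id))
  cat(sprintf("  %d harmonized cis-SNPs after clumping, median n = %s\n",
              nrow(x$variants), format(x$n_median)))
  for (m in names(x$weights)) {
    cat(sprintf("  %-9s %4d non-zero weight(s)\n", m, nrow(x$weights[[m]]$entries)))
  }
  invisible(x)
}

#' @export
summary.grex_fit <- function(object, ...) {
  W <- coef(object)
  out <- data.frame(
    method = colnames(W),
    n_nonzero = apply(W, 2, function(w) sum(w != 0)),
    max_abs_weight = apply(W, 2, function(w) if (all(w == 0)) 0 else max(abs(w))),
    row.names = NULL
  )
  cat(sprintf("gene %s: %d SNPs, %d method(s)\n", object$gene_id, nrow(W), ncol(W)))
  print(out)
  invisible(out)
}

#' Extract trained eQTL weights
#'
#' @param object a `grex_fit`.
#' @param ... unused.
#' @return m x methods matrix of weights on the standardized scale (zeros
#'   included), rows named by variant key.
#' @export
coef.grex_fit <- function(object, ...) {
  rec <- object$variants
  keys <- variant_key(rec$chrom, rec$pos, rec$ref, rec$alt)
  W <- matrix(0, nrow(rec), length(object$weights),
              dimnames = list(keys, names(object$weights)))
  for (m in names(object$weights)) {
    e <- object$weights[[m]]$entries
    W[match(variant_key(e$chrom, e$pos, e$ref, e$alt), keys), m] <- e$weight
  }
  W
}

#' Impute GReX in new samples
#'
#' @param object a `grex_fit`.
#' @param newdata a `genotype_panel` (standardized internally) or an
#'   already-standardized matrix whose columns follow `variant_meta`.
#' @param variant_meta variant table for matrix input.
#' @param ... unused.
#' @return samples x methods matrix of imputed GReX.
#' @export
predict.grex_fit <- function(object, newdata, variant_meta = NULL, ...) {
  if (inherits(newdata, "genotype_panel")) {
    std <- standardize(newdata)
    X <- std$X
    variant_meta <- std$meta
  } else {
    X <- as.matrix(newdata)
    if (is.null(variant_meta)) stop("variant_meta required for matrix input")
  }
  out <- matrix(NA_real_, nrow(X), length(object$weights),
                dimnames = list(NULL, names(object$weights)))
  for (m in names(object$weights)) {
    g <- impute_grex(X, object$weights[[m]], variant_meta)
    out[, m] <- if (is.null(g)) 0 else g
  }
  out
}

#' Gene-based TWAS over a set of trained genes
#'
#' Runs the summary-statistic association test for every gene and method,
#' optionally applies genomic control per method across genes, and combines
#' the per-method p-values into a Cauchy omnibus p-value per gene. Methods
#' flagged invalid (test R-squared <= 0.01) are excluded from the
#' combination; a gene with no valid method gets no omnibus p-value.
#'
#' @param fits list of `grex_fit` objects (one per gene).
#' @param gwas GWAS summary data.frame (see [read_gwas_sumstats()]); it is
#'   matched to each gene's variants by variant key (allele swaps flip the
#'   GWAS Z sign).
#' @param form `"fusion"` (correlation V, standardized weights) or
#'   `"spredixcan"` (covariance V with per-SNP genotype scales).
#' @param gc_correct apply genomic control per method (default FALSE; in
#'   small simulations the per-method median is too noisy to calibrate on).
#' @param test_r2 optional genes x methods matrix of test R-squared values
#'   used for the valid-model filter.
#' @return data.frame of class `twas_result`: one row per gene with per-method
#'   `z_*` and `p_*` columns, `p_acat` (the omnibus p-value) and
#'   `n_valid_methods`; attribute `lambda_gc` when `gc_correct`.
#' @export
twas_scan <- function(fits, gwas, form = c("fusion", "spredixcan"),
                      gc_correct = FALSE, test_r2 = NULL) {
  form <- match.arg(form)
  gkey <- variant_key(gwas$chrom, gwas$pos, gwas$ref, gwas$alt)
  gkey_swap <- variant_key(gwas$chrom, gwas$pos, gwas$alt, gwas$ref)
  methods <- unique(unlist(lapply(fits, function(f) names(f$weights))))
  genes <- vapply(fits, function(f) f$gene_id, character(1))

  zmat <- matrix(NA_real_, length(fits), length(methods),
                 dimnames = list(genes, methods))
  for (i in seq_along(fits)) {
    fit <- fits[[i]]
    if (nrow(fit$variants) == 0) next
    keys <- variant_key(fit$variants$chrom, fit$variants$pos,
                        fit$variants$ref, fit$variants$alt)
    idx <- match(keys, gkey)
    swp <- match(keys, gkey_swap)
    z <- ifelse(!is.na(idx), gwas$z[idx], ifelse(!is.na(swp), -gwas$z[swp], NA))
    for (m in intersect(methods, names(fit$weights))) {
      w <- coef(fit)[, m]
      use <- which(w != 0 & !is.na(z))
      if (length(use) == 0) next
      V <- fit$ld$R[use, use, drop = FALSE]
      sds <- fit$snp_sd[use]
      if (form == "spredixcan") V <- V * tcrossprod(sds)
      res <- twas_z(w[use], z[use], V, form = form,
                    snp_sd = if (form == "spredixcan") sds else NULL)
      if (!is.null(res)) zmat[i, m] <- res$z
    }
  }

  pmat <- z_to_p(zmat)
  lambda <- rep(1, length(methods))
  names(lambda) <- methods
  if (gc_correct) {
    for (m in methods) {
      gcres <- genomic_control(zmat[, m])
      zmat[, m] <- gcres$z
      pmat[, m] <- gcres$p
      lambda[m] <- gcres$lambda_gc
    }
  }

  valid <- if (is.null(test_r2)) {
    !is.na(pmat)
  } else {
    vm <- filter_valid(test_r2[, methods, drop = FALSE])
    vm & !is.na(pmat)
  }
  p_acat <- rep(NA_real_, length(fits))
  for (i in seq_along(fits)) {
    use <- valid[i, ]
    if (!any(use)) next
    p_acat[i] <- acat_o(pmat[i, use])
  }

  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (m in methods) {
    out[[paste0("z_", m)]] <- zmat[, m]
    out[[paste0("p_", m)]] <- pmat[, m]
  }
  out$n_valid_methods <- rowSums(valid)
  out$p_acat <- p_acat
  attr(out, "lambda_gc") <- lambda
  class(out) <- c("twas_result", "data.frame")
  out
}

#' @export
print.twas_result <- function(x, digits = 3, ...) {
  cat(sprintf("TWAS results for %d gene(s)\n", nrow(x)))
  NextMethod()
  invisible(x)
}
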