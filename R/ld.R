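## LD reference handling: genotype standardization, correlation matrices,
## shrinkage, block partitioning, and greedy LD clumping.

#' Standardize a genotype panel
#'
#' Missing dosages are imputed to the per-SNP mean of observed values, then
#' each column is centred and scaled to sample variance 1 (denominator n).
#' Monomorphic SNPs (zero variance after imputation) are dropped with a
#' warning.
#'
#' @param panel a `genotype_panel`, or a plain numeric matrix.
#' @return list with `X` (standardized n x m matrix), `meta` (variant table
#'   for retained SNPs, NULL for plain-matrix input), `sd` (per-SNP standard
#'   deviation of the raw dosages, denominator n) and `kept` (indices of
#'   retained columns in the input).
#' @export
standardize <- function(panel) {
  X <- if (inherits(panel, "genotype_panel")) panel$dosage else as.matrix(panel)
  n <- nrow(X)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sds <- sqrt(colMeans(Xc^2))
  kept <- which(sds > 0)
  if (length(kept) < ncol(X)) {
    warning(sprintf("dropped %d monomorphic SNP(s)", ncol(X) - length(kept)))
  }
  Xs <- sweep(Xc[, kept, drop = FALSE], 2, sds[kept], "/")
  meta <- if (inherits(panel, "genotype_panel")) panel$variant_meta[kept, , drop = FALSE] else NULL
  list(X = Xs, meta = meta, sd = sds[kept], kept = kept)
}

new_ld_structure <- function(R, blocks, shrinkage_s = 0) {
  structure(list(R = R, blocks = blocks, shrinkage_s = shrinkage_s),
            class = "ld_structure")
}

#' @export
print.ld_structure <- function(x, ...) {
  cat(sprintf("LD structure: %d SNPs in %d block(s), shrinkage s = %g\n",
              nrow(x$R), length(x$blocks), x$shrinkage_s))
  invisible(x)
}

#' Compute an LD correlation matrix from standardized genotypes
#'
#' Returns `R = X'X / n` with the diagonal forced to exactly 1, wrapped in an
#' `ld_structure` holding a single block.
#'
#' @param X_std standardized genotype matrix (see [standardize()]).
#' @return an `ld_structure` with fields `R` (m x m correlation matrix) and
#'   `blocks` (list of SNP index vectors).
#' @export
compute_ld <- function(X_std) {
  n <- nrow(X_std)
  R <- crossprod(X_std) / n
  R <- (R + t(R)) / 2
  diag(R) <- 1
  new_ld_structure(R, list(seq_len(ncol(X_std))))
}

#' Shrink an LD correlation matrix toward the identity
#'
#' `R_s = (1 - s) R + s I`; strictly positive definite for any `s > 0`.
#'
#' @param R_r correlation matrix (or `ld_structure`).
#' @param s shrinkage weight in \[0, 1\].
#' @return matrix (or `ld_structure`) of the same shape.
#' @export
shrink_ld <- function(R_r, s) {
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s > 1) {
    stop("s must be a single number in [0, 1]")
  }
  if (inherits(R_r, "ld_structure")) {
    R_r$R <- shrink_ld(R_r$R, s)
    R_r$shrinkage_s <- s
    return(R_r)
  }
  out <- (1 - s) * R_r
  diag(out) <- diag(out) + s
  out
}

#' Partition SNPs into approximately independent LD blocks
#'
#' Greedy left-to-right split along the genome ordering: SNP `j` starts a new
#' block when its squared correlation with every SNP already in the current
#' block is at most `r2_cross`. Every cross-block pair then satisfies
#' r^2 <= r2_cross by construction on block-banded LD; blocks are contiguous
#' index ranges.
#'
#' @param R correlation matrix (SNPs ordered along the genome) or an
#'   `ld_structure`.
#' @param r2_cross maximal tolerated cross-block squared correlation
#'   (default 0.1).
#' @return list of integer index vectors partitioning `1:m`.
#' @export
partition_blocks <- function(R, r2_cross = 0.1) {
  if (inherits(R, "ld_structure")) R <- R$R
  m <- nrow(R)
  blocks <- list()
  start <- 1L
  if (m == 0) return(blocks)
  for (j in seq_len(m)[-1]) {
    cur <- start:(j - 1L)
    if (max(R[cur, j]^2) <= r2_cross) {
      blocks[[length(blocks) + 1L]] <- cur
      start <- j
    }
  }
  blocks[[length(blocks) + 1L]] <- start:m
  blocks
}

#' Load LD block boundaries from a BED file
#'
#' Accepts a 3-column BED (chrom, start, end; 0-based half-open) of
#' precomputed block boundaries and maps them onto a variant table.
#'
#' @param path BED file path.
#' @param variant_meta data.frame with columns chrom, pos (genome-ordered).
#' @return list of integer index vectors partitioning the SNPs; SNPs not
#'   covered by any interval are placed in singleton blocks.
#' @export
read_ld_blocks <- function(path, variant_meta) {
  bed <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop(sprintf("'%s' is not a 3-column BED file", path))
  names(bed)[1:3] <- c("chrom", "start", "end")
  assign_block <- rep(NA_integer_, nrow(variant_meta))
  for (b in seq_len(nrow(bed))) {
    hit <- as.character(variant_meta$chrom) == as.character(bed$chrom[b]) &
      variant_meta$pos > bed$start[b] & variant_meta$pos <= bed$end[b]
    assign_block[hit & is.na(assign_block)] <- b
  }
  blocks <- list()
  i <- 1L
  while (i <= length(assign_block)) {
    if (is.na(assign_block[i])) {
      blocks[[length(blocks) + 1L]] <- i
      i <- i + 1L
    } else {
      j <- i
      while (j < length(assign_block) && !is.na(assign_block[j + 1L]) &&
             assign_block[j + 1L] == assign_block[i]) j <- j + 1L
      blocks[[length(blocks) + 1L]] <- i:j
      i <- j + 1L
    }
  }
  blocks
}

#' Greedy LD clumping
#'
#' Iterates variants by ascending p-value (ties broken by chrom, pos order);
#' retains the current variant and removes all not-yet-retained variants with
#' squared correlation above `r2_threshold` to it. The result is independent
#' of input row order.
#'
#' @param sumstats an `eqtl_sumstats` (harmonized: records carry a
#'   `panel_index` or are in the same order as `R`'s SNPs) or a data.frame
#'   with columns chrom, pos, p.
#' @param R correlation matrix over the sumstats' variants (or `ld_structure`).
#' @param r2_threshold clumping R^2 threshold (default 0.99).
#' @return integer vector of retained variant indices (row indices into the
#'   records), in ascending index order.
#' @export
ld_clump <- function(sumstats, R, r2_threshold = 0.99) {
  rec <- if (inherits(sumstats, "eqtl_sumstats")) sumstats$records else sumstats
  if (inherits(R, "ld_structure")) R <- R$R
  m <- nrow(rec)
  stopifnot(nrow(R) == m)
  if (m == 0) return(integer(0))
  ord <- order(rec$p, as.character(rec$chrom), rec$pos)
  alive <- rep(TRUE, m)
  retained <- logical(m)
  for (i in ord) {
    if (!alive[i]) next
    retained[i] <- TRUE
    alive[i] <- FALSE
    drop <- alive & (R[, i]^2 > r2_threshold)
    alive[drop] <- FALSE
  }
  which(retained)
}
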