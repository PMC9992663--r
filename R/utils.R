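#' Soft-thresholding operator
#'
#' `soft_threshold(x, lambda)` returns `sign(x) * max(|x| - lambda, 0)`,
#' the proximal operator of the L1 penalty. Vectorised over `x`.
#'
#' @param x numeric vector.
#' @param lambda non-negative threshold.
#' @return numeric vector of the same length as `x`.
#' @export
soft_threshold <- function(x, lambda) {
  stopifnot(is.numeric(x), is.numeric(lambda), lambda >= 0)
  sign(x) * pmax(abs(x) - lambda, 0)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (e.g. 0.05).
#' @param n_tests number of independent tests adjusted for.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni(0.05, 20000) # 2.5e-6, the genome-wide TWAS threshold for 20K genes
#' @export
bonferroni <- function(alpha, n_tests) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  if (!is.numeric(n_tests) || length(n_tests) != 1L || n_tests < 1) {
    stop("n_tests must be a single number >= 1")
  }
  alpha / n_tests
}

# Two-sided normal p-value from a Z statistic.
z_to_p <- function(z) 2 * stats::pnorm(-abs(z))

# Derive a child RNG seed from a master seed and a string label, keeping the
# result a valid 32-bit R integer. Used for per-gene seeding so that parallel
# or reordered execution cannot change results.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

# Variant key used everywhere a unique SNP identity is needed.
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Cholesky factor of a symmetric matrix with escalating diagonal jitter.
# Returns the upper-triangular factor; errors after `tries` escalations.
chol_jitter <- function(A, jitter = 1e-3, tries = 3L) {
  for (k in 0:tries) {
    eps <- if (k == 0) 0 else jitter * 10^(k - 1)
    U <- tryCatch(chol(A + diag(eps, nrow(A))), error = function(e) NULL)
    if (!is.null(U)) return(U)
  }
  stop("matrix not positive definite after jitter escalation")
}
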