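# Shared fixture builders and independent oracle implementations.

# Write a tab-delimited eQTL summary file and return its path.
write_eqtl_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A small eQTL table: gene G1 on chrom 1, with controllable positions.
toy_eqtl_df <- function(pos = c(1500000L, 1600000L, 1700000L),
                        z = c(2, -1, 0.5), n = rep(3000L, length(pos)),
                        gene = "G1", chrom = "1",
                        ref = rep("A", length(pos)), alt = rep("G", length(pos))) {
  data.frame(CHROM = chrom, POS = pos, REF = ref, ALT = alt, GENE = gene,
             Z = z, P = 2 * pnorm(-abs(z)), N = n, stringsAsFactors = FALSE)
}

# Standardized genotype matrix with AR(1)-ish LD, plus its correlation matrix.
toy_ld_matrix <- function(m, n = 400, rho = 0.5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  if (m > 1) for (j in 2:m) X[, j] <- rho * X[, j - 1] + sqrt(1 - rho^2) * X[, j]
  X <- sweep(X, 2, colMeans(X))
  X <- sweep(X, 2, sqrt(colMeans(X^2)), "/")
  list(X = X, R = {
    R <- crossprod(X) / n
    diag(R) <- 1
    R
  })
}

# Independent greedy-clumping oracle: a literal, list-based transcription of
# the rule (sort by p with positional tie-break; retain head; delete r2 > thr
# partners; repeat), kept structurally different from ld_clump().
clump_oracle <- function(p, chrom, pos, R, r2_threshold) {
  remaining <- order(p, chrom, pos)
  retained <- integer(0)
  while (length(remaining) > 0) {
    head_i <- remaining[1]
    retained <- c(retained, head_i)
    remaining <- remaining[-1]
    if (length(remaining) > 0) {
      partners <- vapply(remaining, function(j) R[head_i, j]^2 > r2_threshold,
                         logical(1))
      remaining <- remaining[!partners]
    }
  }
  sort(retained)
}

# Independent greedy gene-pruning oracle (same style).
prune_oracle <- function(grex, p, r2_cut) {
  remaining <- order(p)
  kept <- integer(0)
  while (length(remaining) > 0) {
    g <- remaining[1]
    kept <- c(kept, g)
    remaining <- remaining[-1]
    if (length(remaining) > 0) {
      drop <- vapply(remaining, function(h) {
        r <- suppressWarnings(cor(grex[, g], grex[, h]))
        !is.na(r) && r^2 > r2_cut
      }, logical(1))
      remaining <- remaining[!drop]
    }
  }
  sort(kept)
}

# Proximal-gradient solver for the explicit lassosum objective
# f(w) = (1-s) w'Rw + s w'w - 2 beta'w + 2 lambda ||w||_1 over one block;
# a generic convex-optimization oracle independent of coordinate descent.
proxgrad_lasso <- function(beta, R, s, lambda, iters = 50000, tol = 1e-12) {
  m <- length(beta)
  A <- (1 - s) * R + s * diag(m)
  L <- 2 * max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / L
  w <- numeric(m)
  for (i in seq_len(iters)) {
    grad <- 2 * (A %*% w) - 2 * beta
    w_new <- sign(w - step * grad) * pmax(abs(w - step * grad) - 2 * lambda * step, 0)
    if (max(abs(w_new - w)) < tol) {
      w <- w_new
      break
    }
    w <- w_new
  }
  as.numeric(w)
}

# One small trained simulation replicate reused by several tests.
small_replicate <- function(seed = 3, m = 100, p_causal = 0.01, h_e2 = 0.1,
                            n_gwas = 40000, methods = c("PT_001", "PT_05", "LASSOSUM",
                                                        "SDPR", "PRSCS")) {
  cfg <- sim_config(m_snps = m, p_causal = p_causal, h_e2 = h_e2, n_gwas = n_gwas)
  simulate_twas_replicate(cfg, methods = methods, n_gwas_reps = 2, seed = seed)
}
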