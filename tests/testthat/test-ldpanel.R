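test_that("standardize centres, scales, imputes, and drops monomorphic SNPs", {
  X <- cbind(c(0, 1, 2), c(1, 1, 1), c(0, 2, NA))
  meta <- data.frame(chrom = "1", pos = 1:3, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  panel <- genotype_panel(X, meta)
  expect_warning(std <- standardize(panel), "monomorphic")
  expect_equal(ncol(std$X), 2)               # constant column dropped
  expect_equal(std$kept, c(1L, 3L))
  expect_equal(colMeans(std$X), c(0, 0))
  expect_equal(colMeans(std$X^2), c(1, 1))   # variance 1, denominator n
  # NA imputed to the observed mean (1) before scaling
  expect_equal(std$X[3, 2], 0)
})

test_that("compute_ld returns X'X/n with exact unit diagonal", {
  toy <- toy_ld_matrix(3, n = 200, rho = 0, seed = 2)
  X <- cbind(toy$X, toy$X[, 1])              # duplicated column
  ld <- compute_ld(X)
  expect_equal(diag(ld$R), rep(1, 4))
  expect_equal(ld$R[1, 4], 1)                # duplicate -> correlation 1
  expect_true(isSymmetric(ld$R))
  # orthogonal columns -> identity
  Xo <- qr.Q(qr(matrix(rnorm(40), 10, 4))) * sqrt(10)
  expect_equal(compute_ld(Xo)$R, diag(4), tolerance = 1e-12)
  # two independent columns at n = 1000: |r| below the ~3.2 sd bound 0.1
  set.seed(11)
  Xi <- scale(matrix(rnorm(2000), 1000, 2)) * sqrt(1000 / 999)
  expect_lt(abs(compute_ld(Xi)$R[1, 2]), 0.1)
})

test_that("shrink_ld forms (1-s) R + s I and validates s", {
  R <- matrix(c(1, 0.8, 0.8, 1), 2)
  expect_equal(shrink_ld(R, 1), diag(2))
  expect_equal(shrink_ld(R, 0), R)
  expect_equal(shrink_ld(R, 0.5)[1, 2], 0.4)
  expect_error(shrink_ld(R, 1.2), "0, 1")
  expect_error(shrink_ld(R, -0.1), "0, 1")
  # strictly positive definite for s > 0 even from a singular R
  Rs <- shrink_ld(matrix(1, 3, 3), 0.2)
  expect_true(all(eigen(Rs, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("partition_blocks recovers block structure", {
  expect_equal(partition_blocks(diag(5)), as.list(1:5))
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.6
  R[3, 4] <- R[4, 3] <- 0.7
  expect_equal(partition_blocks(R), list(1:2, 3:4))
  R_one <- matrix(0.9, 4, 4)
  diag(R_one) <- 1
  expect_equal(partition_blocks(R_one), list(1:4))
  # every cross-block pair obeys the r2 bound; reassembly loses nothing
  toy <- toy_ld_matrix(40, n = 300, rho = 0.6, seed = 7)
  blocks <- partition_blocks(toy$R, 0.1)
  expect_equal(sort(unlist(blocks)), 1:40)
  for (a in seq_along(blocks)) {
    for (b in seq_along(blocks)) {
      if (a == b) next
      expect_true(all(toy$R[blocks[[a]], blocks[[b]]]^2 <= 0.1))
    }
  }
})

test_that("ld_clump follows the greedy rule and is order-invariant", {
  # two perfectly correlated variants: keep the more significant one
  R2 <- matrix(c(1, 1, 1, 1), 2)
  rec <- data.frame(chrom = "1", pos = 1:2, p = c(1e-5, 1e-3))
  expect_equal(ld_clump(rec, R2, 0.99), 1L)
  # r^2 = 0.98 < 0.99: both kept
  R98 <- matrix(c(1, sqrt(0.98), sqrt(0.98), 1), 2)
  expect_equal(ld_clump(rec, R98, 0.99), c(1L, 2L))
  # 10 variants vs the independent oracle, several random LD draws
  for (seed in 1:5) {
    toy <- toy_ld_matrix(10, n = 50, rho = 0.8, seed = seed)
    set.seed(seed + 100)
    rec10 <- data.frame(chrom = "1", pos = 1:10, p = runif(10))
    got <- ld_clump(rec10, toy$R, 0.5)
    expect_equal(got, clump_oracle(rec10$p, rec10$chrom, rec10$pos, toy$R, 0.5))
    # row-order invariance: permute, map back
    perm <- sample(10)
    got_perm <- ld_clump(rec10[perm, ], toy$R[perm, perm], 0.5)
    expect_equal(sort(perm[got_perm]), got)
  }
})

test_that("PLINK bed/bim/fam round-trips dosages including missing values", {
  set.seed(9)
  n <- 13; m <- 7                            # n not divisible by 4 on purpose
  X <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  X[2, 3] <- NA
  meta <- data.frame(chrom = "1", pos = 1000L + seq_len(m), ref = "A", alt = "G",
                     id = paste0("rs", seq_len(m)), stringsAsFactors = FALSE)
  panel <- genotype_panel(X, meta, paste0("ind", seq_len(n)))
  prefix <- tempfile()
  write_plink(panel, prefix)
  back <- read_plink(prefix)
  expect_equal(back$dosage, X)
  expect_equal(back$sample_ids, panel$sample_ids)
  expect_equal(back$variant_meta$pos, meta$pos)
  # region query
  sub <- read_plink(prefix, region = list("1", 1002, 1004))
  expect_equal(ncol(sub$dosage), 3)
  expect_equal(sub$dosage, X[, 2:4])
})

test_that("read_ld_blocks maps BED intervals onto variants", {
  meta <- data.frame(chrom = "1", pos = c(100L, 150L, 250L, 300L, 900L))
  bed <- data.frame(chrom = "1", start = c(0L, 200L), end = c(200L, 400L))
  path <- tempfile(fileext = ".bed")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  blocks <- read_ld_blocks(path, meta)
  expect_equal(blocks, list(1:2, 3:4, 5L))
})
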