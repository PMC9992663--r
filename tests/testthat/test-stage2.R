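test_that("impute_grex computes X w over the variant intersection", {
  meta <- data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  X <- matrix(c(1, -1, 0, 0.5, 0.5, -1), 3, 2)
  w <- stats::setNames(c(0.5, -0.5), c("1:1:A:G", "1:2:A:G"))
  expect_equal(impute_grex(X, w, meta), as.numeric(X %*% c(0.5, -0.5)))
  # all weights zero -> GReX all zero
  w0 <- stats::setNames(c(0, 0), names(w))
  expect_equal(impute_grex(X, w0, meta), rep(0, 3))
  # single SNP with weight 1 reproduces that genotype column
  w1 <- stats::setNames(1, "1:2:A:G")
  expect_equal(impute_grex(X, w1, meta), X[, 2])
  # empty intersection is a no-gene signal
  w_miss <- stats::setNames(1, "2:9:A:G")
  expect_null(impute_grex(X, w_miss, meta))
})

test_that("twas_z reproduces hand-computed statistics and edge cases", {
  # one SNP, w = 1, z = 3
  r1 <- twas_z(1, 3, matrix(1, 1, 1))
  expect_equal(r1$z, 3)
  expect_equal(r1$p, 2 * (1 - pnorm(3)))
  # two independent SNPs, w = (1,1), z = (2,2): Z_g = 4 / sqrt(2)
  r2 <- twas_z(c(1, 1), c(2, 2), diag(2))
  expect_equal(r2$z, 4 / sqrt(2))
  # degenerate quadratic form and empty SNP set are no-test signals
  expect_null(twas_z(numeric(0), numeric(0), matrix(0, 0, 0)))
  expect_null(twas_z(c(0, 0), c(1, 1), diag(2)))
})

test_that("correlation and covariance forms coincide for unit genotype scales", {
  toy <- toy_ld_matrix(6, seed = 13)
  set.seed(13)
  w <- rnorm(6, sd = 0.2)
  z <- rnorm(6, sd = 1.5)
  f <- twas_z(w, z, toy$R, form = "fusion")
  s <- twas_z(w, z, toy$R, form = "spredixcan", snp_sd = rep(1, 6))
  expect_equal(f$z, s$z, tolerance = 1e-12)
  # and they differ once the scales do
  sds <- seq(0.8, 1.3, length.out = 6)
  V_cov <- toy$R * tcrossprod(sds)
  s2 <- twas_z(w, z, V_cov, form = "spredixcan", snp_sd = sds)
  expect_false(isTRUE(all.equal(f$z, s2$z)))
})

test_that("twas_z is invariant to simultaneous allele-coding sign flips", {
  toy <- toy_ld_matrix(8, seed = 14)
  set.seed(14)
  w <- rnorm(8, sd = 0.2)
  z <- rnorm(8, sd = 1.5)
  base <- twas_z(w, z, toy$R)
  for (rep in 1:5) {
    flip <- sample(c(-1, 1), 8, replace = TRUE)
    V_f <- toy$R * tcrossprod(flip)
    got <- twas_z(w * flip, z * flip, V_f)
    expect_equal(got$z, base$z, tolerance = 1e-12)
  }
})

test_that("genomic control scales statistics to a median p of 0.5", {
  # a z-set whose median z^2 is exactly the chi-square(1) median constant
  z <- sqrt(0.45494 * c(0.2, 0.5, 0.7, 0.9, 0.95, 1, 1.3, 1.6, 2, 3, 1.1))
  gc1 <- genomic_control(z)
  expect_equal(gc1$lambda_gc, 1)
  expect_equal(gc1$p, 2 * pnorm(-abs(z)))
  # doubling every z quadruples lambda and leaves adjusted p identical
  gc2 <- genomic_control(2 * z)
  expect_equal(gc2$lambda_gc, 4 * gc1$lambda_gc)
  expect_equal(gc2$p, gc1$p, tolerance = 1e-12)
  # median adjusted p is 0.5 up to the 4-decimal truncation of the constant
  expect_lt(abs(median(gc2$p) - 0.5), 1e-4)
  # standard-normal null: lambda ~ 1
  set.seed(15)
  gc3 <- genomic_control(rnorm(1e5))
  expect_equal(gc3$lambda_gc, 1, tolerance = 0.02)
  # fewer than 10 genes: skipped with a warning
  expect_warning(gc4 <- genomic_control(rnorm(5)), "fewer than 10")
  expect_equal(gc4$lambda_gc, 1)
})

test_that("acat_o combines p-values on the Cauchy scale", {
  expect_equal(acat_o(rep(0.5, 4)), 0.5)
  for (q in c(0.01, 0.3, 0.9)) {
    expect_equal(acat_o(rep(q, 7)), q, tolerance = 1e-12)  # fixed point
  }
  # agreement with direct high-precision evaluation of the same formula
  p <- c(1e-8, 0.5, 0.5, 0.5, 0.5)
  T_oracle <- (1 / (1e-8 * pi)) / 5          # tan((0.5 - p)pi) -> 1/(p pi) tail
  p_oracle <- 0.5 - atan(T_oracle) / pi
  expect_equal(signif(acat_o(p), 3), signif(p_oracle, 3))
  # Cauchy-combination bound: p_acat <= k * min(p), to first order in min(p)
  # (the companion p-values perturb the bound at relative order min(p) * k)
  set.seed(16)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    p <- c(10^runif(1, -12, -4), runif(k - 1, 0.05, 0.95))
    expect_lte(acat_o(p), k * min(p) * 1.01)
  }
  # empty input is a no-test signal; NAs are dropped
  expect_null(acat_o(NA_real_))
  expect_equal(acat_o(c(0.5, NA)), 0.5)
})

test_that("filter_valid applies the strict R2 > 0.01 rule", {
  expect_true(filter_valid(0.011))
  expect_false(filter_valid(0.01))           # boundary excluded
  expect_true(filter_valid(0.30))
  expect_equal(filter_valid(c(0.005, 0.02)), c(FALSE, TRUE))
})

test_that("prune_independent matches the brute-force greedy rule", {
  # identical GReX: keep only the smaller p
  g <- matrix(rnorm(50), 50, 1)[, c(1, 1)]
  expect_equal(prune_independent(g, c(1e-8, 1e-4)), 1L)
  # uncorrelated GReX: keep both
  set.seed(17)
  g2 <- matrix(rnorm(2000), 1000, 2)
  expect_equal(prune_independent(g2, c(1e-8, 1e-4)), c(1L, 2L))
  # 5-gene correlated chain vs the independent oracle
  for (seed in 1:5) {
    set.seed(seed)
    base <- rnorm(200)
    G <- sapply(seq(0, 1, length.out = 5), function(a) {
      a * base + sqrt(1 - a^2) * rnorm(200)
    })
    p <- runif(5)
    expect_equal(prune_independent(G, p), prune_oracle(G, p, 0.5))
  }
})

test_that("bonferroni divides the error rate", {
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_error(bonferroni(0.05, 0))
})

test_that("twas_scan ties the pieces together over trained genes", {
  reps <- lapply(c(31, 32), function(s) small_replicate(seed = s, m = 60))
  fits <- lapply(reps, function(r) r$fit)
  fits[[1]]$gene_id <- "GA"
  fits[[2]]$gene_id <- "GB"
  # build a GWAS table from the first gene's variants (second gene's SNPs
  # overlap by construction since positions coincide)
  v <- fits[[1]]$variants
  set.seed(33)
  gwas <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                     z = rnorm(nrow(v), sd = 2), n = 50000L,
                     stringsAsFactors = FALSE)
  res <- twas_scan(fits, gwas)
  expect_s3_class(res, "twas_result")
  expect_equal(nrow(res), 2)
  expect_true(all(c("p_PRSCS", "p_SDPR", "p_acat") %in% names(res)))
  ok <- !is.na(res$p_acat)
  expect_true(any(ok))
  # the omnibus p is consistent with acat_o over the per-method p-values
  pm <- as.numeric(res[1, paste0("p_", names(fits[[1]]$weights))])
  expect_equal(res$p_acat[1], acat_o(pm[is.finite(pm)]))
  # valid-model filter: all-invalid gene gets no omnibus p
  r2 <- matrix(0.001, 2, length(fits[[1]]$weights),
               dimnames = list(NULL, names(fits[[1]]$weights)))
  res2 <- twas_scan(fits, gwas, test_r2 = r2)
  expect_true(all(is.na(res2$p_acat)))
  expect_equal(res2$n_valid_methods, c(0L, 0L))
})
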