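test_that("genotype simulation is seeded and respects the LD dial", {
  cfg0 <- sim_config(n_train = 1000L, n_test = 1000L, m_snps = 200L, ld_rho = 0,
                     seed = 21L)
  g1 <- simulate_genotypes(cfg0)
  g2 <- simulate_genotypes(cfg0)
  expect_identical(g1$train$dosage, g2$train$dosage)     # seeded determinism
  expect_identical(g1$test$dosage, g2$test$dosage)
  expect_true(all(g1$train$dosage %in% 0:2))
  # rho = 0: 100 adjacent pairs essentially uncorrelated at n = 2000
  X <- standardize(rbind(g1$train$dosage, g1$test$dosage))$X
  r_adj <- vapply(1:100, function(j) cor(X[, j], X[, j + 1]), numeric(1))
  expect_true(all(abs(r_adj) < 0.1))
  # rho = 0.9: adjacent squared correlation clearly above 0.3
  cfg9 <- sim_config(n_train = 1000L, n_test = 1000L, m_snps = 50L, ld_rho = 0.9,
                     seed = 22L)
  g9 <- simulate_genotypes(cfg9)
  X9 <- standardize(rbind(g9$train$dosage, g9$test$dosage))$X
  r2_adj <- vapply(1:49, function(j) cor(X9[, j], X9[, j + 1])^2, numeric(1))
  expect_gt(median(r2_adj), 0.3)
  # sampled MAFs stay in range
  expect_true(all(g9$maf >= 0.05 & g9$maf <= 0.5))
})

test_that("expression simulation enforces the causal-count and heritability rules", {
  cfg <- sim_config(n_train = 1000L, n_test = 1000L, m_snps = 1000L,
                    p_causal = 0.001, h_e2 = 0.05, seed = 23L)
  g <- simulate_genotypes(cfg)
  X <- standardize(rbind(g$train$dosage, g$test$dosage))$X
  set.seed(23)
  tr <- simulate_expression(X, cfg)
  # p_causal = 0.001, m = 1000 -> exactly one causal SNP
  expect_equal(length(tr$causal_indices), 1L)
  # empirical variance of X w equals h_e2 exactly after rescaling
  gvec <- as.numeric(X %*% tr$w_true)
  expect_equal(mean((gvec - mean(gvec))^2), 0.05, tolerance = 1e-12)
  # realized variance ratio close to h_e2 at n = 2000
  ratio <- 0.05 / (0.05 + var(tr$expression - gvec))
  expect_lt(abs(ratio - 0.05), 0.01)
  # denser architecture: round rule
  cfg2 <- sim_config(m_snps = 500L, p_causal = 0.01, seed = 24L)
  g2 <- simulate_genotypes(cfg2)
  X2 <- standardize(rbind(g2$train$dosage, g2$test$dosage))$X
  set.seed(24)
  tr2 <- simulate_expression(X2, cfg2)
  expect_equal(length(tr2$causal_indices), 5L)
  # h_e2 = 0: zero effects, pure-noise expression still produced
  cfg0 <- sim_config(m_snps = 50L, h_e2 = 0, seed = 25L)
  g0 <- simulate_genotypes(cfg0)
  X0 <- standardize(rbind(g0$train$dosage, g0$test$dosage))$X
  set.seed(25)
  tr0 <- simulate_expression(X0, cfg0)
  expect_true(all(tr0$w_true == 0))
  expect_gt(var(tr0$expression), 0)
})

test_that("single-SNP summary statistics match an OLS oracle", {
  toy <- toy_ld_matrix(20, n = 250, rho = 0.4, seed = 26)
  set.seed(26)
  e <- 0.3 * toy$X[, 5] + rnorm(250)
  ss <- eqtl_sumstats_from_individual(toy$X, e)
  e_std <- as.numeric(scale(e)) * sqrt(250 / 249)
  for (j in c(1, 5, 9, 14, 20)) {
    fit <- lm(e_std ~ toy$X[, j])
    expect_equal(ss$records$beta_marginal[j], unname(coef(fit)[2]), tolerance = 1e-8)
    expect_equal(ss$records$z[j], unname(summary(fit)$coefficients[2, "t value"]),
                 tolerance = 1e-8)
  }
  # e exactly equal to a genotype column: unit weight, vanishing p
  ss1 <- eqtl_sumstats_from_individual(toy$X, toy$X[, 3])
  expect_equal(ss1$records$beta_marginal[3], 1, tolerance = 1e-12)
  expect_lt(ss1$records$p[3], 1e-100)
  # independent noise: no |z| above 4 among 100 SNPs (fixed seed)
  toy2 <- toy_ld_matrix(100, n = 568, rho = 0.5, seed = 28)
  set.seed(1280)  # independent stream for the null expression
  ss2 <- eqtl_sumstats_from_individual(toy2$X, rnorm(568))
  expect_true(all(abs(ss2$records$z) < 4))
})

test_that("GWAS Z-scores follow the stated multivariate normal", {
  m <- 6
  cfg <- sim_config(m_snps = m, n_gwas = 50000L, h_p2 = 0.025)
  # null effects: componentwise mean within 3 SE of zero
  set.seed(28)
  Z0 <- simulate_gwas_z(rep(0, m), diag(m), cfg, n_reps = 10000)
  se <- 1 / sqrt(10000)
  expect_true(all(abs(rowMeans(Z0)) < 3 * se))
  # single causal SNP, identity LD: mean of Z_j is w_j sqrt(n h_p2)
  w <- c(0.2, rep(0, m - 1))
  set.seed(29)
  Z1 <- simulate_gwas_z(w, diag(m), cfg, n_reps = 10000)
  expect_equal(rowMeans(Z1)[1], 0.2 * sqrt(50000 * 0.025), tolerance = 3 * se / 0.2 * 0.2 + 0.05)
  # empirical covariance approaches Sigma entrywise
  toy <- toy_ld_matrix(m, n = 400, rho = 0.6, seed = 30)
  set.seed(30)
  Z2 <- simulate_gwas_z(rep(0, m), toy$R, cfg, n_reps = 10000)
  expect_true(max(abs(cov(t(Z2)) - toy$R)) < 0.05)
})

test_that("test_r2 and power_and_type1 behave as stated", {
  set.seed(31)
  x <- rnorm(100)
  expect_equal(test_r2(x, x), 1)
  expect_equal(test_r2(-x, x), 1)            # squared correlation
  y <- rnorm(1000); z <- rnorm(1000)
  expect_lt(test_r2(y, z), 0.02)             # independent vectors
  const <- test_r2(rep(1, 10), rnorm(10))
  expect_equal(as.numeric(const), 0)
  expect_true(attr(const, "constant"))
  expect_error(test_r2(rnorm(5), rnorm(6)), "length mismatch")

  expect_equal(power_and_type1(rep(1e-8, 10), 2.5e-6), 1)
  expect_equal(power_and_type1(rep(0.5, 10), 2.5e-6), 0)
  set.seed(32)
  expect_lt(abs(power_and_type1(runif(1e5), 0.05) - 0.05), 0.002)
})

test_that("gene-level power is non-decreasing in the GWAS sample size", {
  rep1 <- small_replicate(seed = 41, m = 100, p_causal = 0.01, h_e2 = 0.1)
  fit <- rep1$fit
  w <- coef(fit)[, "SDPR"]
  Sigma <- fit$ld$R
  # truth vector restricted to the clumped SNP set (original index from pos)
  orig_idx <- (fit$variants$pos - 1000000L) / 1000L
  w_true <- rep1$truth$w_true[orig_idx]
  power_at <- function(n_gwas, seed) {
    cfg <- sim_config(m_snps = length(w), n_gwas = n_gwas, h_p2 = 0.025)
    set.seed(seed)
    Z <- simulate_gwas_z(w_true, Sigma, cfg, n_reps = 2000)
    zg <- as.numeric(crossprod(w, Z)) / sqrt(drop(crossprod(w, Sigma %*% w)))
    mean(2 * pnorm(-abs(zg)) < 2.5e-6)
  }
  p_small <- power_at(10000, 51)
  p_big <- power_at(40000, 52)
  se <- sqrt(0.25 / 2000)
  expect_gte(p_big, p_small - 2 * se)
})

test_that("whole replicates are deterministic given the seed", {
  r1 <- small_replicate(seed = 61, m = 50)
  r2 <- small_replicate(seed = 61, m = 50)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$r2, r2$r2)
  expect_identical(coef(r1$fit), coef(r2$fit))
})
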