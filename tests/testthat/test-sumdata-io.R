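test_that("read_eqtl_sumstats filters the cis-window and computes n_median", {
  df <- toy_eqtl_df(pos = c(500000L, 1500000L, 1600000L, 1700000L, 3500000L),
                    z = c(1, 2, -1, 0.5, 3),
                    n = c(2900L, 3000L, 3100L, 3200L, 3300L))
  path <- write_eqtl_fixture(df)
  ss <- read_eqtl_sumstats(path, "G1", list("1", 1000000, 3000000))
  expect_s3_class(ss, "eqtl_sumstats")
  expect_equal(nrow(ss$records), 3)         # 5 rows, 3 inside the window
  expect_equal(ss$n_median, 3100L)          # median of 3000, 3100, 3200
  expect_equal(ss$records$z, c(2, -1, 0.5))
  expect_equal(ss$records$beta_marginal, c(2, -1, 0.5) / sqrt(3100))
})

test_that("read_eqtl_sumstats enforces the schema and uniqueness invariants", {
  df <- toy_eqtl_df()
  dup <- rbind(df, df[1, ])
  expect_error(read_eqtl_sumstats(write_eqtl_fixture(dup), "G1",
                                  list("1", 1, 5e6)),
               "duplicate variant")
  missing_col <- df[, setdiff(names(df), "POS")]
  expect_error(read_eqtl_sumstats(write_eqtl_fixture(missing_col), "G1",
                                  list("1", 1, 5e6)),
               "missing required column")
  # neither Z nor (BETA, SE) present
  no_effect <- df[, setdiff(names(df), "Z")]
  expect_error(read_eqtl_sumstats(write_eqtl_fixture(no_effect), "G1",
                                  list("1", 1, 5e6)),
               "Z column or both BETA and SE")
  # empty gene is a signal, not an error
  ss <- read_eqtl_sumstats(write_eqtl_fixture(df), "NOSUCH", list("1", 1, 5e6))
  expect_equal(nrow(ss$records), 0)
})

test_that("the (BETA, SE) dialect derives Z, and NA-effect rows are dropped", {
  df <- toy_eqtl_df()
  df$Z <- NULL
  df$BETA <- c(0.04, -0.02, NA)
  df$SE <- c(0.02, 0.02, 0.01)
  path <- write_eqtl_fixture(df)
  expect_message(ss <- read_eqtl_sumstats(path, "G1", list("1", 1, 5e6)),
                 "dropped 1 row")
  expect_equal(ss$records$z, c(2, -1))
})

test_that("marginal_std_beta matches z / sqrt(n) and is linear in z", {
  expect_equal(marginal_std_beta(2, 400), 0.1)
  expect_equal(marginal_std_beta(0, 12345), 0)
  expect_equal(marginal_std_beta(-3, 900), -0.1)
  expect_error(marginal_std_beta(1, 1), "n_median")
  # linearity / scale equivariance
  set.seed(1)
  z <- rnorm(20)
  for (c_mult in c(-2, 0.5, 10)) {
    expect_equal(marginal_std_beta(c_mult * z, 500),
                 c_mult * marginal_std_beta(z, 500))
  }
})

test_that("harmonize keeps, flips, and drops variants correctly", {
  panel <- data.frame(chrom = "1", pos = c(100L, 200L, 300L, 400L, 500L, 500L),
                      ref = c("G", "A", "C", "A", "A", "A"),
                      alt = c("A", "G", "T", "T", "G", "C"),
                      stringsAsFactors = FALSE)
  gwas <- data.frame(chrom = "1", pos = c(100L, 200L, 300L, 400L, 500L, 600L),
                     ref = c("A", "A", "C", "A", "A", "A"),
                     alt = c("G", "G", "T", "T", "G", "G"),
                     z = c(1.5, 2, 1, 1, 1, 1), n = 1000L,
                     stringsAsFactors = FALSE)
  h <- harmonize(gwas, panel)
  # pos 100: (A,G) vs panel (G,A) -> kept with z = -1.5 and alleles swapped
  # pos 200: perfect match, unchanged
  # pos 300: C/T fine (not ambiguous); pos 400 A/T ambiguous -> dropped
  # pos 500: multi-allelic in panel -> dropped; pos 600 unmatched -> dropped
  expect_equal(h$report[["flipped"]], 1)
  expect_equal(h$report[["kept"]], 2)
  expect_equal(h$report[["ambiguous"]], 1)
  expect_equal(h$report[["multiallelic"]], 1)
  expect_equal(h$report[["unmatched"]], 1)
  out <- h$sumstats
  expect_equal(out$pos, c(100L, 200L, 300L))
  expect_equal(out$z, c(-1.5, 2, 1))
  expect_equal(out$ref[1], "G")              # flipped to panel orientation
  expect_equal(out$alt[1], "A")
})

test_that("harmonize is idempotent", {
  panel <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                      ref = c("G", "A", "C"), alt = c("A", "G", "T"),
                      stringsAsFactors = FALSE)
  gwas <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                     ref = c("A", "A", "C"), alt = c("G", "G", "T"),
                     z = c(1.5, 2, -1), n = 1000L, stringsAsFactors = FALSE)
  once <- harmonize(gwas, panel)$sumstats
  twice <- harmonize(once[, names(gwas)], panel)$sumstats
  expect_equal(twice[, names(gwas)], once[, names(gwas)])
})

test_that("weight files round-trip exactly", {
  e <- data.frame(chrom = "1", pos = c(11L, 22L), ref = c("A", "C"),
                  alt = c("G", "T"), weight = c(0.25, -0.125),
                  stringsAsFactors = FALSE)
  w <- sumtwas:::new_eqtl_weights("G1", "PRSCS", e)
  path <- tempfile(fileext = ".tsv")
  write_weights(w, path)
  back <- read_weights(path)
  expect_equal(back$gene_id, "G1")
  expect_equal(back$method, "PRSCS")
  expect_equal(back$entries, w$entries)
  # empty weight set: header-only file, read back as empty list
  w0 <- sumtwas:::new_eqtl_weights("G1", "PRSCS", e[0, ])
  path0 <- tempfile(fileext = ".tsv")
  write_weights(w0, path0)
  expect_equal(length(readLines(path0)), 1L)
  expect_equal(read_weights(path0), list())
  # non-finite weights are refused
  e_bad <- e
  e_bad$weight[1] <- Inf
  expect_error(write_weights(sumtwas:::new_eqtl_weights("G1", "PRSCS", e_bad), path),
               "non-finite")
})

test_that("stored p and z are mutually consistent in generated summary data", {
  set.seed(42)
  toy <- toy_ld_matrix(30, n = 500, rho = 0.3, seed = 5)
  e <- rnorm(500) + 0.4 * toy$X[, 7]
  ss <- eqtl_sumstats_from_individual(toy$X, e)
  z_back <- qnorm(1 - ss$records$p / 2)
  expect_equal(signif(z_back, 3), signif(abs(ss$records$z), 3))
})
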