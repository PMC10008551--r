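# Loading, quality control, group summaries and the rank test.

test_that("load_samples parses numbers, Unicode minus, and blanks", {
  s <- load_samples(tiny_samples_csv())
  expect_equal(nrow(s), 4)
  expect_equal(s$d13C_coll[1], -19.0)  # Unicode minus in the file
  expect_true(is.na(s$d13C_carb[3]))
  expect_true(is.na(s$d18O_carb_vpdb[3]))
  expect_type(s$d15N, "double")
})

test_that("load_samples rejects duplicate ids and bad numerics", {
  p <- write_sample_csv(c("sample_id,d13C_coll", "TC8,-19", "TC8,-20"))
  expect_error(load_samples(p), "TC8")
  p2 <- write_sample_csv(c("sample_id,d13C_coll", "A,-19", "B,oops"))
  expect_error(load_samples(p2), "row 2")
  expect_error(load_samples(p2), "d13C_coll")
})

test_that("collagen QC flags C/N range, yield, and missingness", {
  qc <- qc_config()
  good <- assess_collagen_quality(list(cn_atomic = 3.2, d13C_carb = -12))
  expect_true(good$collagen_ok)
  expect_true(good$carbonate_ok)
  expect_length(good$reasons, 0)

  bad <- assess_collagen_quality(list(cn_atomic = 3.8, d13C_carb = -12))
  expect_false(bad$collagen_ok)
  expect_false(bad$carbonate_ok)  # exclusion propagates to carbonate
  expect_true("cn_out_of_range" %in% bad$reasons)
  expect_true("collagen_failed_so_carbonate_excluded" %in% bad$reasons)

  lowy <- assess_collagen_quality(list(cn_atomic = 3.2,
                                       collagen_yield = 0.2))
  expect_false(lowy$collagen_ok)
  expect_true("insufficient_collagen" %in% lowy$reasons)

  nocn <- assess_collagen_quality(list(d13C_coll = -19))
  expect_false(nocn$collagen_ok)
  expect_true("missing_measurement" %in% nocn$reasons)
})

test_that("QC flag invariants hold across random samples", {
  set.seed(1)
  for (i in 1:200) {
    s <- list(cn_atomic = sample(c(NA, runif(1, 2.5, 4.2)), 1),
              collagen_yield = sample(c(NA, runif(1, 0, 5)), 1),
              d13C_carb = sample(c(NA, -12), 1))
    f <- assess_collagen_quality(s)
    if (!f$collagen_ok) expect_false(f$carbonate_ok)
    expect_identical(length(f$reasons) == 0,
                     f$collagen_ok && f$carbonate_ok)
  }
})

test_that("apply_qc reports per-group exclusion percentages", {
  n <- 134
  df <- data.frame(sample_id = sprintf("H%03d", 1:n), species = "human",
                   cn_atomic = c(rep(3.2, n - 16), rep(3.9, 15), 3.2),
                   collagen_yield = c(rep(5, n - 1), 0.2),
                   d13C_coll = -19)
  res <- apply_qc(df)
  expect_equal(res$report$groups$human$n_excluded, 16)
  expect_equal(res$report$groups$human$percent_excluded, 11.9)
  expect_equal(nrow(res$accepted) + res$report$n_excluded, n)

  allpass <- apply_qc(data.frame(sample_id = c("a", "b"), species = "human",
                                 cn_atomic = c(3.2, 3.3), d13C_coll = -19))
  expect_equal(allpass$report$groups$human$percent_excluded, 0)

  ten <- apply_qc(data.frame(sample_id = letters[1:10], species = "human",
                             cn_atomic = c(rep(3.2, 9), 4.1),
                             d13C_coll = -19))
  expect_equal(ten$report$groups$human$percent_excluded, 10.0)
})

test_that("no collagen-failed sample can reach a carbonate summary", {
  df <- data.frame(sample_id = c("a", "b", "c"), species = "human",
                   site = "T", cn_atomic = c(3.2, 3.9, 3.3),
                   d13C_coll = c(-19, -18, -20),
                   d13C_carb = c(-12, -5, -13))
  res <- apply_qc(df)
  sm <- summarize_groups(res$accepted, "site", "d13C_carb")
  expect_equal(sm$n, 2)
  expect_equal(sm$mean, -12.5)  # the -5 from the failed sample is gone
})

test_that("group summaries match hand and spreadsheet-style oracles", {
  df <- data.frame(sample_id = 1:2, g = "x", v = c(-19, -21))
  sm <- summarize_groups(df, "g", "v")
  expect_equal(sm$mean, -20)
  expect_equal(sm$sd, sqrt(2))
  expect_equal(c(sm$min, sm$max), c(-21, -19))

  # 5-value table: moments frozen from an independent hand computation
  v5 <- c(-18.2, -19.1, -19.6, -20.3, -18.8)
  df5 <- data.frame(sample_id = 1:5, g = "x", v = v5)
  sm5 <- summarize_groups(df5, "g", "v")
  expect_equal(sm5$mean, -19.2)
  expect_equal(sm5$sd, 0.7968689, tolerance = 1e-6)  # sqrt(2.54/4)
})

test_that("group summaries are invariant to row order and skip NAs", {
  set.seed(7)
  df <- data.frame(sample_id = 1:20,
                   site = sample(c("A", "B"), 20, TRUE),
                   v = c(NA, rnorm(19)))
  a <- summarize_groups(df, "site", "v")
  b <- summarize_groups(df[sample(20), ], "site", "v")
  expect_equal(a, b)
  expect_equal(sum(a$n), 19)
})

test_that("U statistic equals brute-force enumeration (property)", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney_u(c(1, 3), c(2, 4))$U, 1)
  set.seed(42)
  for (i in 1:100) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    a <- sample(1:6, n1, TRUE); b <- sample(1:6, n2, TRUE)  # ties likely
    expect_equal(mann_whitney_u(a, b)$U, brute_force_u(a, b))
  }
})

test_that("exact p-values agree with wilcox.test when tie-free", {
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1))
    res <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(res$method, "exact_enumeration")
    expect_equal(res$p_two_sided, ref$p.value, tolerance = 1e-12)
    expect_true(res$U >= 0 && res$U <= res$n1 * res$n2)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("large tie-free samples switch to the normal approximation", {
  set.seed(3)
  a <- rnorm(120); b <- rnorm(120) + 0.3   # n1*n2 > 10000
  res <- mann_whitney_u(a, b)
  expect_equal(res$method, "normal_approx_tie_corrected")
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res$p_two_sided, ref$p.value, tolerance = 1e-6)
})
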