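# Synthetic-data generators: determinism, planted structure, round trips.

test_that("generators are pure functions of (spec, seed)", {
  spec <- population_spec(n_humans = 40, n_fauna = 8, seed = 3)
  pr <- build_problem(default_sources(), default_proxies())
  a <- generate_consumers(spec, pr)
  b <- generate_consumers(spec, pr)
  expect_identical(a, b)
  expect_identical(generate_mobility(spec, n = 30),
                   generate_mobility(spec, n = 30))
  expect_identical(generate_isoscape_points(n = 50, seed = 9),
                   generate_isoscape_points(n = 50, seed = 9))
  c <- generate_consumers(spec, pr, seed = 4)
  expect_false(identical(a$samples$d13C_coll, c$samples$d13C_coll))
})

test_that("zero noise makes proxies equal the forward model exactly", {
  spec <- population_spec(n_humans = 12, qc_failure_rate = 0,
                          proxy_noise_sd = c(d13C_coll = 0, d15N = 0,
                                             d13C_carb = 0),
                          nursing_offset = 0, seed = 5)
  pr <- build_problem(default_sources(), default_proxies())
  g <- generate_consumers(spec, pr)
  for (i in seq_len(nrow(g$samples))) {
    al <- as.numeric(g$truth[i, pr$source_names])
    mu <- forward_model(al, pr)
    expect_equal(g$samples$d13C_coll[i], mu[["d13C_coll"]])
    expect_equal(g$samples$d15N[i], mu[["d15N"]])
  }
})

test_that("QC failures are injected at the configured binomial rate", {
  spec <- population_spec(seed = 1)
  pr <- build_problem(default_sources(), default_proxies())
  fails <- vapply(1:60, function(s) {
    g <- generate_consumers(spec, pr, seed = s)
    sum(apply_qc(g$samples)$flagged$collagen_ok == FALSE)
  }, numeric(1))
  # 60 replicates of Binomial(134, 0.12): test the mean failure count
  bt <- binom.test(sum(fails), 60 * 134, p = 0.12)
  expect_gt(bt$p.value, 0.001)
  # and the generator's truth labels agree with the QC module's verdicts
  g <- generate_consumers(spec, pr, seed = 2)
  flags <- apply_qc(g$samples)$flagged$collagen_ok
  expect_identical(!flags, g$truth$qc_fail)
})

test_that("mobility water values survive the conversion round trip", {
  spec <- population_spec(resident_sd = 0, seed = 7)
  mob <- generate_mobility(spec, n = 20)
  back <- carbonate_vpdb_to_water(mob$d18O_carb_vpdb)$value
  expect_equal(back, mob$d18O_water_true, tolerance = 1e-9)
  # sd 0 residents all sit exactly on the resident mean
  res <- mob$d18O_water_true[mob$origin_class == "resident"]
  expect_true(all(res == -7.7))
})

test_that("trimmed clustering recovers the planted mobility labels", {
  spec <- population_spec(seed = 11)
  mob <- generate_mobility(spec, n = 66, seed = 11)
  water <- carbonate_vpdb_to_water(mob$d18O_carb_vpdb)$value
  sol <- fit_trimmed_1d(water, k = 2, trim_fraction = 0.05,
                        restarts = 20, seed = 11)
  # map the planted classes onto the fitted labels
  pred <- ifelse(is.na(sol$assignments), "outlier",
                 ifelse(sol$assignments == which.max(sol$means),
                        "resident", "migrant"))
  acc <- mean(pred == mob$origin_class)
  expect_gte(acc, 0.95)
  # cluster means close to the planted component means
  expect_lt(abs(max(sol$means) - -7.7), 0.5)
  expect_lt(abs(min(sol$means) - -12.9), 0.7)
})

test_that("dietary cluster geometry carries the two mixing lines", {
  spec <- population_spec(n_humans = 400, qc_failure_rate = 0,
                          nursing_offset = 0, seed = 13)
  pr <- build_problem(default_sources(), default_proxies())
  g <- generate_consumers(spec, pr)
  s <- g$samples
  c1 <- g$truth$cluster == 1
  # C3->C4 line: d13C and d15N negatively correlated
  expect_lt(cor(s$d13C_coll[c1], s$d15N[c1]), -0.2)
  # C3->marine line: positively correlated
  expect_gt(cor(s$d13C_coll[!c1], s$d15N[!c1]), 0.2)
  # truth alphas on the simplex
  A <- as.matrix(g$truth[, pr$source_names])
  expect_true(all(abs(rowSums(A) - 1) < 1e-9) && all(A >= 0))
})

test_that("simulate_dataset writes a complete, reloadable fixture set", {
  out <- file.path(tempdir(), "simfix")
  paths <- simulate_dataset(out, population_spec(n_humans = 30,
                                                 n_fauna = 5, seed = 2))
  for (p in paths) expect_true(file.exists(p))
  s <- load_samples(paths$samples)
  expect_equal(nrow(s), 35)
  iso <- read.csv(paths$isoscape_points)
  expect_named(iso, c("lon", "lat", "mean", "se"))
})

test_that("simulated mixing targets are calibrated for the sampler", {
  # single replicate sanity check of the generative helper: targets finite
  # and within a plausible per-mil window of the forward prediction
  pr <- build_problem(default_sources(), default_proxies())
  al <- rep(1 / 7, 7)
  tg <- simulate_targets(pr, al, seed = 3)
  mu <- forward_model(al, pr)
  expect_true(all(abs(tg - mu) < 6))
})
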