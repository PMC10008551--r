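# Bayesian dietary mixing: problem validation, forward model, sampler.

test_that("build_problem validates structure and feasibility", {
  pr <- build_problem(default_sources(), default_proxies(),
                      list(mixing_constraint(c("C3 plants" = 1), 0.3)))
  expect_s3_class(pr, "mixing_problem")
  expect_length(pr$source_names, 7)

  expect_error(
    build_problem(default_sources(), default_proxies(),
                  list(mixing_constraint(c("C3 plants" = 1), 0.8),
                       mixing_constraint(c("C4 cereals" = 1), 0.8))),
    "infeasible")
  # no constraints: uniform simplex prior accepted
  expect_s3_class(build_problem(default_sources(), default_proxies()),
                  "mixing_problem")
  expect_error(food_source("x", list(d13C = c(-20, 0.5)),
                           list(d13C = c(-25, 0.5)),
                           c(protein = 0.6, energy = 0.6)),
               "sum to 1")
})

test_that("forward model reduces correctly in symmetric cases", {
  s1 <- food_source("A", protein = list(d13C = c(-24, 0)),
                    energy = list(d13C = c(-28, 0)),
                    c(protein = 0.5, energy = 0.5), 0)
  s2 <- food_source("B", protein = list(d13C = c(-12, 0)),
                    energy = list(d13C = c(-14, 0)),
                    c(protein = 0.5, energy = 0.5), 0)
  px <- mixing_proxy("d13C", "d13C", -19, 1, 0, 0,
                     c(protein = 0.6, energy = 0.4))
  # single source, zero offset: prediction equals the routed signal mix
  p1 <- build_problem(list(s1), list(px))
  expect_equal(unname(forward_model(1, p1)), 0.6 * -24 + 0.4 * -28)
  # equal concentrations, alpha = (.5,.5): arithmetic mean of signals
  p2 <- build_problem(list(s1, s2), list(px))
  expect_equal(unname(forward_model(c(0.5, 0.5), p2)),
               0.6 * mean(c(-24, -12)) + 0.4 * mean(c(-28, -14)))
})

test_that("forward model weights by caloric concentration", {
  # c_protein = .8 vs .2: hand-computed concentration-weighted means
  s1 <- food_source("A", protein = list(d13C = c(-24, 0)),
                    energy = list(d13C = c(-28, 0)),
                    c(protein = 0.8, energy = 0.2), 0)
  s2 <- food_source("B", protein = list(d13C = c(-12, 0)),
                    energy = list(d13C = c(-14, 0)),
                    c(protein = 0.2, energy = 0.8), 0)
  px <- mixing_proxy("d13C", "d13C", -19, 1, 1.5, 0,
                     c(protein = 0.5, energy = 0.5))
  pr <- build_problem(list(s1, s2), list(px))
  prot <- (0.5 * 0.8 * -24 + 0.5 * 0.2 * -12) / (0.5 * 0.8 + 0.5 * 0.2)
  ener <- (0.5 * 0.2 * -28 + 0.5 * 0.8 * -14) / (0.5 * 0.2 + 0.5 * 0.8)
  expect_equal(unname(forward_model(c(0.5, 0.5), pr)),
               1.5 + 0.5 * prot + 0.5 * ener)
})

test_that("posterior draws live on the simplex and honour constraints", {
  pr <- build_problem(default_sources(), default_proxies(),
                      list(mixing_constraint(c("C3 plants" = 1), 0.3),
                           mixing_constraint(c("marine fish" = 1), 0.25,
                                             "<=")))
  post <- sample_posterior(pr, chains = 2, iter = 8000, seed = 21)
  d <- post$draws
  expect_true(all(abs(rowSums(d) - 1) < 1e-9))
  expect_true(all(d >= 0))
  expect_true(all(d[, "C3 plants"] >= 0.3 - 1e-12))
  expect_true(all(d[, "marine fish"] <= 0.25 + 1e-12))
})

test_that("identical seed and settings give identical draws", {
  pr <- toy_two_source(-21.5)
  a <- sample_posterior(pr, chains = 2, iter = 1500, seed = 5)
  b <- sample_posterior(pr, chains = 2, iter = 1500, seed = 5)
  expect_identical(a$draws, b$draws)
  c <- sample_posterior(pr, chains = 2, iter = 1500, seed = 6)
  expect_false(identical(a$draws, c$draws))
})

test_that("noise-free two-source problem recovers the analytic mixture", {
  truth <- 0.7
  target <- truth * -26 + (1 - truth) * -11  # linear mixing, equal conc.
  pr <- toy_two_source(target)
  post <- sample_posterior(pr, chains = 4, iter = 6000, seed = 11)
  m <- mean(post$draws[, "A"])
  mcse <- sd(post$draws[, "A"]) / sqrt(min(post$diagnostics$ess))
  expect_lt(abs(m - truth), 3 * max(mcse, 1e-4))
  expect_true(all(post$diagnostics$rhat < 1.05))
})

test_that("single-source posterior is the point mass alpha = 1", {
  s <- food_source("only", protein = list(d13C = c(-20, 0.5)),
                   energy = list(d13C = c(-24, 0.5)))
  pr <- build_problem(list(s), default_proxies(d15N = NULL,
                                               d13C_carb = NULL))
  post <- sample_posterior(pr, chains = 2, iter = 200, seed = 1)
  expect_true(all(post$draws == 1))
  sm <- summarize_posterior(post)
  expect_equal(sm$sources$mean, 1)
  expect_equal(sm$sources$ci95_low, 1)
  expect_equal(sm$sources$ci95_high, 1)
})

test_that("posterior summaries are empirical quantiles of the draws", {
  pr <- toy_two_source(-18.5)
  post <- sample_posterior(pr, chains = 2, iter = 2000, seed = 3)
  # overwrite with 10 hand-written draws and check against quantile()
  x <- c(0.1, 0.15, 0.2, 0.3, 0.42, 0.5, 0.61, 0.7, 0.8, 0.95)
  post$draws <- cbind(A = x, B = 1 - x)
  sm <- summarize_posterior(post)$sources
  expect_equal(sm$ci95_low[1], unname(quantile(x, 0.025)))
  expect_equal(sm$ci68_high[1], unname(quantile(x, 0.84)))
  expect_equal(sm$median[1], median(x))
  # 68% interval nested in the 95% interval
  expect_true(all(sm$ci68_low >= sm$ci95_low & sm$ci68_high <= sm$ci95_high))
  # degenerate posterior: zero-width intervals
  post$draws <- cbind(A = rep(0.4, 8), B = rep(0.6, 8))
  smd <- summarize_posterior(post)$sources
  expect_equal(smd$ci95_low, smd$ci95_high)
})

test_that("posterior predictive means cover synthetic targets", {
  pr0 <- build_problem(default_sources(), default_proxies())
  al <- c(0.45, 0.12, 0.05, 0.1, 0.13, 0.05, 0.1)
  tg <- simulate_targets(pr0, al, seed = 8)
  pr <- build_problem(default_sources(),
                      default_proxies(d13C_coll = c(tg[["d13C_coll"]], 0.5),
                                      d15N = c(tg[["d15N"]], 0.5),
                                      d13C_carb = c(tg[["d13C_carb"]], 0.8)))
  post <- sample_posterior(pr, chains = 2, iter = 5000, seed = 8)
  pred <- forward_model(colMeans(post$draws), pr)
  expect_lt(abs(pred[["d13C_coll"]] - tg[["d13C_coll"]]), 2)
  expect_lt(abs(pred[["d15N"]] - tg[["d15N"]]), 2)
  expect_lt(abs(pred[["d13C_carb"]] - tg[["d13C_carb"]]), 3)
})
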