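# Isoscape smoothing and probabilistic residence assignment.

small_grid <- function() grid_spec(5, 25, 36, 50, cell = 1)

test_that("a constant field yields a constant predictive surface", {
  set.seed(2)
  pts <- data.frame(lon = runif(30, 5, 25), lat = runif(30, 36, 50),
                    mean = -7.1, se = 0.1)
  iso <- fit_isoscape(pts, small_grid(), seed = 1)
  expect_true(all(abs(iso$mean - -7.1) < 1e-6))
  expect_true(all(iso$sd > 0))
})

test_that("the smoother interpolates observations with tiny noise", {
  set.seed(3)
  fld <- default_field(se = 0.001)
  pts <- generate_isoscape_points(fld, 80, seed = 4)
  pts$se <- 0.001
  iso <- fit_isoscape(pts, small_grid(), seed = 2)
  pr <- iso$predict(pts$lon[1:10], pts$lat[1:10])
  expect_true(all(abs(pr$mean - pts$mean[1:10]) < 0.01))
})

test_that("a known smooth surface is recovered with low grid RMSE", {
  fld <- default_field(se = 0.3)
  pts <- generate_isoscape_points(fld, 200, seed = 5)
  iso <- fit_isoscape(pts, small_grid(), seed = 3)
  qq <- expand.grid(lon = iso$grid$lon, lat = iso$grid$lat)
  truth <- matrix(fld$fun(qq$lon, qq$lat), length(iso$grid$lon))
  rmse <- sqrt(mean((iso$mean - truth)^2))
  expect_lt(rmse, 0.5)
})

test_that("degenerate coincident designs are rejected", {
  pts <- data.frame(lon = rep(10, 12), lat = rep(40, 12), mean = -7,
                    se = 0.1)
  expect_error(fit_isoscape(pts, small_grid()), "coincident")
})

test_that("local estimates interpolate the grid bilinearly", {
  set.seed(6)
  pts <- generate_isoscape_points(default_field(), 100, seed = 7)
  iso <- fit_isoscape(pts, small_grid(), seed = 4)
  gx <- iso$grid$lon; gy <- iso$grid$lat
  # at a cell centre: that cell's value
  expect_equal(unname(local_estimate(iso, gx[3], gy[4])["mean"]),
               iso$mean[3, 4])
  # midpoint of two adjacent centres: their arithmetic mean
  expect_equal(unname(local_estimate(iso, (gx[3] + gx[4]) / 2, gy[4])["mean"]),
               mean(iso$mean[3:4, 4]))
})

test_that("residence maps normalize and respond to distance in d18O", {
  set.seed(8)
  pts <- generate_isoscape_points(default_field(), 100, seed = 9)
  iso <- fit_isoscape(pts, small_grid(), seed = 5)
  m <- assign_residence(iso, -8, 2)
  expect_equal(sum(m$prob), 1, tolerance = 1e-9)
  expect_true(all(m$prob >= 0))

  # constant isoscape -> uniform map
  ptsc <- data.frame(lon = runif(30, 5, 25), lat = runif(30, 36, 50),
                     mean = -7, se = 0.1)
  isoc <- fit_isoscape(ptsc, small_grid(), seed = 6)
  mc <- assign_residence(isoc, -9, 2)
  expect_lt(diff(range(mc$prob)), 1e-6)

  # monotone in |measured - mu| when cell sds are equal
  iso2 <- iso
  iso2$sd[] <- 0.5
  m2 <- assign_residence(iso2, -8, 1)
  d <- abs(-8 - iso2$mean)
  expect_gte(cor(as.numeric(-d), as.numeric(m2$prob), method = "spearman"),
             0.999)
})

test_that("two-cell weights match the closed form", {
  # construct a minimal isoscape by hand: mu = (-8, -13), sigma = 0
  iso <- structure(list(grid = list(lon = c(0, 1), lat = 0.5, cell = 1),
                        mean = matrix(c(-8, -13), 2, 1),
                        sd = matrix(1e-12, 2, 1)),
                   class = "isoscape")
  m <- assign_residence(iso, -8, 1)
  ratio <- m$prob[1, 1] / m$prob[2, 1]
  expect_equal(ratio, exp(0) / exp(-12.5), tolerance = 1e-9)
})

test_that("widening measurement uncertainty never sharpens the map", {
  set.seed(10)
  pts <- generate_isoscape_points(default_field(), 100, seed = 11)
  iso <- fit_isoscape(pts, small_grid(), seed = 7)
  entropy <- function(p) -sum(p * log(p + 1e-300))
  sig <- c(0.5, 1, 2, 4)
  ent <- vapply(sig, function(s)
    entropy(assign_residence(iso, -11, s)$prob), numeric(1))
  expect_true(all(diff(ent) >= -1e-9))
})

test_that("a planted origin is recovered at the argmax (or neighbour)", {
  fld <- default_field(se = 0.1)
  pts <- generate_isoscape_points(fld, 150, seed = 12)
  iso <- fit_isoscape(pts, small_grid(), seed = 8)
  origin <- c(lon = 8.5, lat = 47.5)   # cool end of the field
  measured <- fld$fun(origin["lon"], origin["lat"])
  m <- assign_residence(iso, measured, 0.5)
  top <- map_summary(m, 0.5)$argmax
  # the surface is a gradient: the argmax must sit on the truth isopleth
  expect_lt(abs(fld$fun(top["lon"], top["lat"]) - measured), 0.3)
})

test_that("map summaries accumulate cells greedily", {
  iso <- structure(list(grid = list(lon = c(0, 1), lat = c(0, 1), cell = 1),
                        mean = matrix(0, 2, 2), sd = matrix(1, 2, 2)),
                   class = "isoscape")
  m <- assign_residence(iso, 0, 1)
  m$prob <- matrix(c(0.5, 0.3, 0.15, 0.05), 2, 2)
  s <- map_summary(m, 0.8)
  expect_equal(nrow(s$cells), 2)
  expect_equal(s$cells$prob, c(0.5, 0.3))
  expect_equal(s$coverage, 0.8)
  # uniform map at level 1 returns every cell
  mu <- m; mu$prob <- matrix(0.25, 2, 2)
  expect_equal(nrow(map_summary(mu, 1)$cells), 4)
  # delta-like map: single cell
  md <- m; md$prob <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(nrow(map_summary(md, 0.95)$cells), 1)
})
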