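# Drinking-water d18O baseline and residence assignment. The baseline is a
# smoothed surface fit to point predictions (e.g. precipitation-model grid
# nodes) by Gaussian-process regression with a Matern-5/2 kernel and
# per-point observation noise; residence probability compares a measured
# (converted) human water value against the surface cell by cell.

.matern52 <- function(D, ell) {
  s <- sqrt(5) * D / ell
  (1 + s + s^2 / 3) * exp(-s)
}

#' Specify a regular lon/lat grid
#'
#' Cell-centred lattice: the first centre sits half a cell inside the
#' bounding box. Defaults span western Europe.
#'
#' @param lon_min,lon_max,lat_min,lat_max bounding box, decimal degrees.
#' @param cell cell size in degrees.
#' @return list with cell-centre coordinate vectors and the box.
#' @export
grid_spec <- function(lon_min = -10, lon_max = 30, lat_min = 35,
                      lat_max = 60, cell = 0.5) {
  stopifnot(lon_max > lon_min, lat_max > lat_min, cell > 0)
  list(lon = seq(lon_min + cell / 2, lon_max - cell / 2, by = cell),
       lat = seq(lat_min + cell / 2, lat_max - cell / 2, by = cell),
       cell = cell,
       box = c(lon_min = lon_min, lon_max = lon_max,
               lat_min = lat_min, lat_max = lat_max))
}

#' Fit a smoothed d18O-water baseline surface
#'
#' Gaussian-process regression of point mean values on (lon, lat) with a
#' Matern-5/2 covariance, a constant mean profiled out by generalized least
#' squares, observation noise equal to each point's squared standard error
#' plus a fitted nugget, and hyperparameters (signal sd, range, nugget)
#' chosen by marginal-likelihood maximization. Distances are Euclidean in
#' degrees.
#'
#' @param points data.frame with columns `lon`, `lat`, `mean`, `se`.
#' @param grid a [grid_spec()].
#' @param seed integer seed for the optimizer's multistart.
#' @param n_starts optimizer restarts.
#' @return an `isoscape` object: per-cell predictive `mean` and `sd`
#'   matrices (lon x lat), the grid, and fit metadata.
#' @export
fit_isoscape <- function(points, grid = grid_spec(), seed = 1,
                         n_starts = 5) {
  stopifnot(all(c("lon", "lat", "mean", "se") %in% names(points)))
  stopifnot(nrow(points) >= 10)
  stopifnot(all(points$lon >= -180 & points$lon <= 180),
            all(points$lat >= -90 & points$lat <= 90),
            all(points$se >= 0))
  X <- cbind(points$lon, points$lat)
  if (max(dist(X)) < 1e-9) stop("degenerate design: all points coincident")
  y <- points$mean
  n <- length(y)
  D <- as.matrix(dist(X))
  se2 <- points$se^2

  nll <- function(par) {
    sf2 <- exp(par[1]); ell <- exp(par[2]); tau2 <- exp(par[3])
    K <- sf2 * .matern52(D, ell) + diag(se2 + tau2, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ones <- rep(1, n)
    Ki1 <- backsolve(ch, forwardsolve(t(ch), ones))
    Kiy <- backsolve(ch, forwardsolve(t(ch), y))
    beta <- sum(Ki1 * y) / sum(Ki1 * ones)
    r <- y - beta
    Kir <- backsolve(ch, forwardsolve(t(ch), r))
    0.5 * sum(r * Kir) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  }

  set.seed(seed)
  sy <- max(sd(y), 1e-3)
  span <- max(D) / 4
  best <- NULL
  starts <- rbind(
    c(log(sy^2), log(span), log(1e-4)),
    matrix(c(log(sy^2) + rnorm(n_starts - 1, 0, 1),
             log(span) + rnorm(n_starts - 1, 0, 1),
             log(sy^2 / 10) + rnorm(n_starts - 1, 0, 1)),
           ncol = 3))
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(optim(starts[i, ], nll, method = "Nelder-Mead",
                        control = list(maxit = 400)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("hyperparameter optimization failed")
  sf2 <- exp(best$par[1]); ell <- exp(best$par[2]); tau2 <- exp(best$par[3])

  K <- sf2 * .matern52(D, ell) + diag(se2 + tau2, n)
  ch <- chol(K)
  ones <- rep(1, n)
  Ki <- chol2inv(ch)
  beta <- as.numeric((ones %*% Ki %*% y) / (ones %*% Ki %*% ones))
  alpha <- Ki %*% (y - beta)

  gp_predict <- function(qlon, qlat) {
    Q <- cbind(qlon, qlat)
    mu <- numeric(nrow(Q)); sdv <- numeric(nrow(Q))
    # chunked cross-covariance keeps memory bounded on large grids
    chunk <- 2000L
    for (s in seq(1, nrow(Q), by = chunk)) {
      idx <- s:min(s + chunk - 1L, nrow(Q))
      Dq <- sqrt(outer(Q[idx, 1], X[, 1], "-")^2 +
                 outer(Q[idx, 2], X[, 2], "-")^2)
      ks <- sf2 * .matern52(Dq, ell)
      mu[idx] <- beta + as.numeric(ks %*% alpha)
      v <- sf2 - rowSums((ks %*% Ki) * ks)
      sdv[idx] <- sqrt(pmax(v, 1e-8))
    }
    list(mean = mu, sd = sdv)
  }

  qq <- expand.grid(lon = grid$lon, lat = grid$lat)
  pr <- gp_predict(qq$lon, qq$lat)
  mean_mat <- matrix(pr$mean, length(grid$lon), length(grid$lat))
  sd_mat <- matrix(pr$sd, length(grid$lon), length(grid$lat))

  structure(list(grid = grid, mean = mean_mat, sd = sd_mat,
                 predict = gp_predict,
                 params = c(signal_sd = sqrt(sf2), range = ell,
                            nugget_sd = sqrt(tau2), mean = beta),
                 n_points = n, seed = seed),
            class = "isoscape")
}

#' @export
print.isoscape <- function(x, ...) {
  cat(sprintf(
    "Isoscape: %d x %d grid (%.1f deg), fit to %d points\n  mean %.2f, signal sd %.2f, range %.2f deg, nugget sd %.3f\n",
    length(x$grid$lon), length(x$grid$lat), x$grid$cell, x$n_points,
    x$params["mean"], x$params["signal_sd"], x$params["range"],
    x$params["nugget_sd"]))
  invisible(x)
}

#' Local baseline estimate at a query point
#'
#' Bilinear interpolation of the gridded predictive mean and sd at
#' (lon, lat); queries outside the grid clamp to the nearest edge cell.
#'
#' @param iso an `isoscape`.
#' @param lon,lat query coordinates, decimal degrees.
#' @return named vector `c(mean, se)`, per mil.
#' @export
local_estimate <- function(iso, lon, lat) {
  interp <- function(M) {
    gx <- iso$grid$lon; gy <- iso$grid$lat
    x <- min(max(lon, gx[1]), gx[length(gx)])
    y <- min(max(lat, gy[1]), gy[length(gy)])
    i <- max(1, min(findInterval(x, gx), length(gx) - 1))
    j <- max(1, min(findInterval(y, gy), length(gy) - 1))
    tx <- (x - gx[i]) / (gx[i + 1] - gx[i])
    ty <- (y - gy[j]) / (gy[j + 1] - gy[j])
    (1 - tx) * (1 - ty) * M[i, j] + tx * (1 - ty) * M[i + 1, j] +
      (1 - tx) * ty * M[i, j + 1] + tx * ty * M[i + 1, j + 1]
  }
  if (length(iso$grid$lon) == 1 || length(iso$grid$lat) == 1)
    stop("grid too small for interpolation")
  c(mean = interp(iso$mean), se = interp(iso$sd))
}

#' Probabilistic residence assignment against an isoscape
#'
#' For each grid cell c with baseline mean `mu_c` and sd `sigma_c`, the
#' unnormalized weight is
#' `exp(-(measured - mu_c)^2 / (2 (sigma_m^2 + sigma_c^2))) /
#'  sqrt(sigma_m^2 + sigma_c^2)`;
#' weights are normalized over the grid to a probability surface. Use the
#' conservative 2 per-mil measurement uncertainty for individuals and the
#' standard error of the cluster mean for cluster averages.
#'
#' @param iso an `isoscape`.
#' @param measured measured (converted) water d18O, per mil.
#' @param sigma_m uncertainty of the measured value, per mil (> 0).
#' @return a `residence_map`: probability matrix on the isoscape grid.
#' @export
assign_residence <- function(iso, measured, sigma_m = 2.0) {
  stopifnot(inherits(iso, "isoscape"), sigma_m > 0)
  v <- sigma_m^2 + iso$sd^2
  lw <- -(measured - iso$mean)^2 / (2 * v) - 0.5 * log(v)
  lw <- lw - max(lw)
  w <- exp(lw)
  structure(list(grid = iso$grid, prob = w / sum(w),
                 measured = measured, sigma_m = sigma_m),
            class = "residence_map")
}

#' @export
print.residence_map <- function(x, ...) {
  top <- map_summary(x, 0.5)
  cat(sprintf(
    "Residence map for %.1f permil (sigma %.1f): argmax at (%.2f, %.2f); %d cells hold 50%% probability\n",
    x$measured, x$sigma_m, top$argmax["lon"], top$argmax["lat"],
    nrow(top$cells)))
  invisible(x)
}

#' Smallest credible cell set of a residence map
#'
#' Greedily accumulates cells in decreasing probability until the requested
#' cumulative level is reached; also reports the argmax cell.
#'
#' @param m a `residence_map`.
#' @param level cumulative probability level in (0, 1].
#' @return list with `cells` (data.frame lon, lat, prob, in decreasing
#'   probability), `coverage` (attained cumulative probability), `argmax`.
#' @export
map_summary <- function(m, level = 0.95) {
  stopifnot(inherits(m, "residence_map"), level > 0, level <= 1)
  p <- as.numeric(m$prob)
  qq <- expand.grid(lon = m$grid$lon, lat = m$grid$lat)
  ord <- order(p, decreasing = TRUE)
  cum <- cumsum(p[ord])
  n_take <- which(cum >= level - 1e-12)[1]
  if (is.na(n_take)) n_take <- length(p)
  sel <- ord[seq_len(n_take)]
  cells <- data.frame(lon = qq$lon[sel], lat = qq$lat[sel], prob = p[sel])
  list(cells = cells, coverage = cum[n_take],
       argmax = c(lon = qq$lon[ord[1]], lat = qq$lat[ord[1]],
                  prob = p[ord[1]]))
}

#' Export an isoscape or residence map as a long-format table
#'
#' @param x an `isoscape` or `residence_map`.
#' @return data.frame with `lon`, `lat`, and `mean`/`sd` or `prob` columns.
#' @export
as_long_table <- function(x) {
  qq <- expand.grid(lon = x$grid$lon, lat = x$grid$lat)
  if (inherits(x, "isoscape")) {
    qq$mean <- as.numeric(x$mean); qq$sd <- as.numeric(x$sd)
  } else if (inherits(x, "residence_map")) {
    qq$prob <- as.numeric(x$prob)
  } else stop("unsupported object")
  qq
}
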