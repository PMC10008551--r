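# Mixture-model clustering for dietary biplots and water d18O:
# (a) 2-D Gaussian mixtures on (d13C_collagen, d15N) fit by EM over a grid
#     of component counts and covariance families, selected by BIC;
# (b) 1-D trimmed Gaussian clustering (classification EM with a
#     concentration step) that sets aside a fixed fraction of
#     lowest-density points as outliers.

.gmm_families <- c("spherical", "diagonal", "full")

# k-means++ seeding on the rows of x (matrix), returns center rows
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1, prob = p), ]
      dn <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, dn)
    }
  }
  centers
}

# log N(x | mu, Sigma) for all rows of x; Sigma 2x2 (or scalar variance list)
.ldmvnorm <- function(x, mu, Sigma) {
  d <- ncol(x)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  xc <- x - matrix(mu, nrow(x), d, byrow = TRUE)
  z <- xc %*% backsolve(ch, diag(d))
  -0.5 * rowSums(z^2) - sum(log(diag(ch))) - d / 2 * log(2 * pi)
}

.cov_constrain <- function(S, family, floor = 1e-6) {
  d <- nrow(S)
  S <- switch(family,
    spherical = diag(rep(mean(diag(S)), d)),
    diagonal = diag(pmax(diag(S), 0), d),
    full = S)
  # variance floor keeps EM away from singularities
  ev <- eigen(S, symmetric = TRUE)
  ev$values <- pmax(ev$values, floor)
  ev$vectors %*% diag(ev$values, d) %*% t(ev$vectors)
}

.gmm_n_params <- function(k, d, family) {
  cov_p <- switch(family, spherical = 1, diagonal = d,
                  full = d * (d + 1) / 2)
  (k - 1) + k * d + k * cov_p
}

# one EM run from a k-means++ start; returns NULL on degeneracy
.gmm_em_once <- function(x, k, family, max_iter = 500, tol = 1e-8,
                         var_floor = 1e-6) {
  n <- nrow(x); d <- ncol(x)
  centers <- .kmeanspp_centers(x, k)
  assign0 <- max.col(-as.matrix(dist(rbind(centers, x)))[-(1:k), 1:k,
                                                         drop = FALSE])
  w <- pmax(tabulate(assign0, k) / n, 1 / n)
  w <- w / sum(w)
  mu <- centers
  S0 <- .cov_constrain(stats::cov(x) + diag(1e-4, d), family, var_floor)
  Sig <- rep(list(S0), k)
  for (j in seq_len(k)) {
    pts <- x[assign0 == j, , drop = FALSE]
    if (nrow(pts) > d) {
      Sj <- stats::cov(pts)
      if (all(is.finite(Sj))) Sig[[j]] <- .cov_constrain(Sj, family, var_floor)
    }
    mu[j, ] <- if (nrow(pts)) colMeans(pts) else centers[j, ]
  }

  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lw <- matrix(NA_real_, n, k)
    for (j in seq_len(k)) {
      ld <- .ldmvnorm(x, mu[j, ], Sig[[j]])
      if (is.null(ld)) return(NULL)
      lw[, j] <- log(w[j]) + ld
    }
    m <- apply(lw, 1, max)
    li <- m + log(rowSums(exp(lw - m)))
    ll <- sum(li)
    ll_trace <- c(ll_trace, ll)
    r <- exp(lw - li)
    nk <- colSums(r)
    # a component collapsing onto fewer points than the dimension+1 rides
    # the variance floor and spikes the likelihood: treat as degenerate
    if (any(nk < d + 1)) return(NULL)
    w <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(r[, j] * x) / nk[j]
      xc <- x - matrix(mu[j, ], n, d, byrow = TRUE)
      Sj <- crossprod(xc * sqrt(r[, j])) / nk[j]
      Sig[[j]] <- .cov_constrain(Sj, family, var_floor)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  # components pinned to the variance floor are singular fits
  for (j in seq_len(k))
    if (min(eigen(Sig[[j]], symmetric = TRUE, only.values = TRUE)$values) <=
        var_floor * 1.001) return(NULL)
  lw <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) lw[, j] <- log(w[j]) + .ldmvnorm(x, mu[j, ], Sig[[j]])
  list(k = k, family = family, weights = w, means = mu, covariances = Sig,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       assignments = max.col(lw))
}

#' Fit Gaussian mixtures by EM and select the model by BIC
#'
#' Runs EM for every combination of component count in `k_range` and
#' covariance family in `families`, each from `restarts` seeded k-means++
#' initializations, and returns the solution minimizing
#' `BIC = -2 logL + p log(n)`. Ties break toward fewer components, then the
#' simpler family. Clusters are relabelled in increasing order of their
#' first-coordinate mean so solutions are deterministic up to the seed.
#'
#' @param points numeric matrix/data.frame (n x d), e.g. columns
#'   `d13C_coll` and `d15N`.
#' @param k_range integer vector of component counts to try.
#' @param families subset of `"spherical"`, `"diagonal"`, `"full"`.
#' @param restarts EM restarts per (k, family).
#' @param seed integer seed (mandatory).
#' @return a `cluster_solution` with `k`, `covariance_family`, `weights`,
#'   `means`, `covariances`, `assignments`, `loglik`, `loglik_trace`,
#'   `bic`, `bic_table`, `n_outliers = 0`, `seed`.
#' @export
fit_gmm_bic <- function(points, k_range = 1:5, families = .gmm_families,
                        restarts = 20, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  x <- as.matrix(points)
  storage.mode(x) <- "double"
  stopifnot(all(is.finite(x)))
  n <- nrow(x)
  if (n < max(k_range) * 3)
    stop("need at least 3 points per candidate component")
  families <- match.arg(families, .gmm_families, several.ok = TRUE)
  set.seed(seed)
  best <- NULL
  bic_rows <- list()
  for (k in sort(k_range)) {
    for (fam in .gmm_families[.gmm_families %in% families]) {
      fit_best <- NULL
      for (r in seq_len(restarts)) {
        f <- .gmm_em_once(x, k, fam)
        if (!is.null(f) &&
            (is.null(fit_best) || f$loglik > fit_best$loglik))
          fit_best <- f
      }
      if (is.null(fit_best)) next
      p <- .gmm_n_params(k, ncol(x), fam)
      bic <- -2 * fit_best$loglik + p * log(n)
      bic_rows[[length(bic_rows) + 1L]] <-
        data.frame(k = k, family = fam, loglik = fit_best$loglik,
                   n_params = p, bic = bic)
      # strict < keeps the first (smaller k, simpler family) on ties
      if (is.null(best) || bic < best$bic - 1e-9) {
        best <- fit_best
        best$bic <- bic
      }
    }
  }
  if (is.null(best)) stop("all EM runs degenerate; check the input data")
  ord <- order(best$means[, 1])
  relab <- match(seq_len(best$k), ord)
  sol <- structure(list(
    k = best$k, covariance_family = best$family,
    weights = best$weights[ord],
    means = best$means[ord, , drop = FALSE],
    covariances = best$covariances[ord],
    assignments = relab[best$assignments],
    outliers = integer(0), n_outliers = 0L,
    loglik = best$loglik, loglik_trace = best$loglik_trace,
    bic = best$bic,
    bic_table = do.call(rbind, bic_rows),
    seed = seed), class = "cluster_solution")
  sol
}

#' Trimmed 1-D Gaussian clustering with outlier flagging
#'
#' Classification EM with a concentration step: at each iteration the
#' `ceiling(trim_fraction * n)` points with the lowest mixture density are
#' set aside as outliers and excluded from the parameter updates, as in
#' trimmed-clustering (tclust-style) estimation. The best of `restarts`
#' seeded runs by trimmed classification likelihood is returned, clusters
#' sorted by increasing mean.
#'
#' @param points numeric vector.
#' @param k number of clusters.
#' @param trim_fraction fraction of points to trim, in `[0, 0.5)`.
#' @param restarts seeded restarts.
#' @param seed integer seed (mandatory).
#' @param equal_var constrain cluster variances to be equal?
#' @return a `cluster_solution`; `assignments` holds `NA` for outliers and
#'   `outliers` their indices.
#' @export
fit_trimmed_1d <- function(points, k = 2, trim_fraction = 0.05,
                           restarts = 20, seed, equal_var = FALSE) {
  if (missing(seed)) stop("a seed is mandatory")
  x <- as.numeric(points)
  stopifnot(all(is.finite(x)), trim_fraction >= 0, trim_fraction < 0.5)
  n <- length(x)
  n_trim <- if (trim_fraction > 0) ceiling(trim_fraction * n) else 0L
  if (2 * k >= n - n_trim)
    stop("too few untrimmed points for the requested number of clusters")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    f <- .trimmed_cem_once(x, k, n_trim, equal_var)
    if (!is.null(f) && (is.null(best) || f$loglik > best$loglik)) best <- f
  }
  if (is.null(best)) stop("all trimmed-EM runs degenerate")
  ord <- order(best$means)
  relab <- match(seq_len(k), ord)
  assignments <- relab[best$assignments]
  assignments[best$outliers] <- NA_integer_
  structure(list(
    k = k, covariance_family = if (equal_var) "equal_var" else "free_var",
    weights = best$weights[ord], means = best$means[ord],
    variances = best$variances[ord],
    assignments = assignments,
    outliers = sort(best$outliers), n_outliers = length(best$outliers),
    trim_fraction = trim_fraction,
    loglik = best$loglik, loglik_trace = best$loglik_trace,
    bic = NA_real_, seed = seed), class = "cluster_solution")
}

.trimmed_cem_once <- function(x, k, n_trim, equal_var, max_iter = 200,
                              var_floor = 1e-6) {
  n <- length(x)
  centers <- as.numeric(.kmeanspp_centers(matrix(x, ncol = 1), k))
  mu <- centers
  s2 <- rep(max(var(x) / k^2, var_floor), k)
  w <- rep(1 / k, k)
  out_idx <- integer(0)
  ll_trace <- numeric(0)
  assign_old <- NULL
  for (it in seq_len(max_iter)) {
    ld <- vapply(seq_len(k), function(j)
      log(w[j]) + dnorm(x, mu[j], sqrt(s2[j]), log = TRUE),
      numeric(n))
    ld <- matrix(ld, n, k)
    best_j <- max.col(ld)
    best_ld <- ld[cbind(seq_len(n), best_j)]
    out_idx <- if (n_trim > 0) order(best_ld)[seq_len(n_trim)] else integer(0)
    keep <- setdiff(seq_len(n), out_idx)
    ll <- sum(best_ld[keep])
    ll_trace <- c(ll_trace, ll)
    nk <- tabulate(best_j[keep], k)
    if (any(nk == 0)) return(NULL)
    for (j in seq_len(k)) {
      xj <- x[keep][best_j[keep] == j]
      mu[j] <- mean(xj)
      s2[j] <- max(if (length(xj) > 1) sum((xj - mu[j])^2) / length(xj)
                   else var_floor, var_floor)
    }
    if (equal_var) s2 <- rep(sum(nk * s2) / sum(nk), k)
    w <- nk / sum(nk)
    if (!is.null(assign_old) && identical(assign_old, best_j) &&
        it > 2) break
    assign_old <- best_j
  }
  list(means = mu, variances = s2, weights = w,
       assignments = best_j, outliers = out_idx,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace)
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Cluster solution: k = %d (%s), n_outliers = %d\n",
              x$k, x$covariance_family, x$n_outliers))
  if (is.matrix(x$means)) print(round(x$means, 2))
  else cat("means:", paste(round(x$means, 2), collapse = ", "), "\n")
  if (!is.na(x$bic)) cat(sprintf("BIC = %.2f\n", x$bic))
  invisible(x)
}

#' Cross-tabulate cluster assignments against a categorical label
#'
#' Returns raw counts and row percentages (percent of each cluster falling
#' in each label category), percentages rounded to whole numbers for
#' reporting while counts keep full information. Outliers (NA assignments)
#' are tabulated as their own `"outlier"` row.
#'
#' @param assignments integer vector of cluster indices (NA = outlier).
#' @param labels categorical vector of the same length.
#' @return list with `counts` (matrix) and `row_percent` (matrix, integers).
#' @export
cross_tabulate <- function(assignments, labels) {
  stopifnot(length(assignments) == length(labels))
  af <- ifelse(is.na(assignments), "outlier",
               paste0("cluster_", assignments))
  counts <- table(factor(af), factor(labels))
  counts <- matrix(counts, nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  rs <- rowSums(counts)
  pct <- counts
  for (i in seq_len(nrow(counts)))
    pct[i, ] <- if (rs[i] > 0) round(100 * counts[i, ] / rs[i]) else 0
  list(counts = counts, row_percent = pct)
}
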