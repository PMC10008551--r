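# Seeded generators that emulate the statistical structure of a medieval
# multi-site skeletal assemblage: two dietary clusters (a C3->C4 protein
# mixing line and a C3->marine line), a resident/migrant water-d18O mixture
# with rare extreme outliers, elevated faunal nitrogen baselines, and a
# configurable collagen QC failure rate. Every generator is a pure function
# of (spec, seed) and emits its ground truth alongside the data; no stage
# of the analysis pipeline reads the truth tables.

#' Specification of a synthetic study population
#'
#' Defaults mirror a three-site assemblage of 134 humans and 21 fauna with
#' roughly 12% collagen QC failures, two dietary clusters, a dominant
#' resident group (water d18O -7.7 +/- 0.8 per mil), a small migrant group
#' (-12.9 +/- 0.9 per mil) and four extreme outliers.
#'
#' @param n_humans,n_fauna sample counts.
#' @param site_probs named probabilities of site membership for humans.
#' @param cluster1_prob probability a human follows the C3->C4 mixing line
#'   (cluster 1); otherwise the C3->marine line (cluster 2).
#' @param qc_failure_rate probability a human sample fails collagen QC.
#' @param proxy_noise_sd named per-proxy measurement noise, per mil.
#' @param resident_fraction fraction of mobility-assessed adults who are
#'   local residents (the rest are migrants, before outliers are added).
#' @param resident_mean,resident_sd,migrant_mean,migrant_sd water d18O
#'   mixture components, per mil.
#' @param outlier_values planted extreme water d18O values, per mil.
#' @param nursing_offset d15N increment added to neonates (breastfeeding
#'   signal); 0 disables.
#' @param seed default seed used when a generator is called without one.
#' @return a `population_spec` list.
#' @export
population_spec <- function(n_humans = 134, n_fauna = 21,
                            site_probs = c(Tertiveri = 0.69,
                                           Montecorvino = 0.24,
                                           "San Lorenzo" = 0.07),
                            cluster1_prob = 15 / 78,
                            qc_failure_rate = 0.12,
                            proxy_noise_sd = c(d13C_coll = 0.4, d15N = 0.7,
                                               d13C_carb = 1.0),
                            resident_fraction = 57 / 62,
                            resident_mean = -7.7, resident_sd = 0.8,
                            migrant_mean = -12.9, migrant_sd = 0.9,
                            outlier_values = c(-17.5, -16.6, -15.8, -3.2),
                            nursing_offset = 1.5,
                            seed = 1L) {
  stopifnot(n_humans >= 1, n_fauna >= 0,
            qc_failure_rate >= 0, qc_failure_rate <= 1,
            cluster1_prob >= 0, cluster1_prob <= 1,
            resident_fraction >= 0, resident_fraction <= 1,
            resident_sd >= 0, migrant_sd >= 0)
  structure(list(n_humans = n_humans, n_fauna = n_fauna,
                 site_probs = site_probs / sum(site_probs),
                 cluster1_prob = cluster1_prob,
                 qc_failure_rate = qc_failure_rate,
                 proxy_noise_sd = proxy_noise_sd,
                 resident_fraction = resident_fraction,
                 resident_mean = resident_mean, resident_sd = resident_sd,
                 migrant_mean = migrant_mean, migrant_sd = migrant_sd,
                 outlier_values = outlier_values,
                 nursing_offset = nursing_offset,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# dietary archetypes over the seven default sources (simplex vectors).
# Cluster 1 interpolates C3-dominated -> C4-heavy (negative d13C/d15N
# correlation); cluster 2 interpolates C3-dominated -> marine-enriched
# (positive correlation).
.archetypes <- function(src_names) {
  a <- function(...) {
    v <- setNames(numeric(length(src_names)), src_names)
    vals <- c(...)
    v[names(vals)] <- vals
    v / sum(v)
  }
  list(
    c3_base = a("C3 plants" = 0.76, "C4 cereals" = 0.04, cattle = 0.02,
                ovicaprid = 0.05, pig = 0.08, poultry = 0.02,
                "marine fish" = 0.01),
    c4_heavy = a("C3 plants" = 0.73, "C4 cereals" = 0.20, cattle = 0.005,
                 ovicaprid = 0.02, pig = 0.02, poultry = 0.005,
                 "marine fish" = 0.005),
    marine_heavy = a("C3 plants" = 0.69, "C4 cereals" = 0.03, cattle = 0.02,
                     ovicaprid = 0.05, pig = 0.08, poultry = 0.02,
                     "marine fish" = 0.055)
  )
}

#' Generate synthetic human consumers with known dietary contributions
#'
#' Each human draws a true contribution vector along one of two mixing
#' lines, gets proxies from the deterministic forward model plus Gaussian
#' measurement noise, and fails collagen QC (C/N ratio pushed outside the
#' acceptance window) with the configured probability. Ground-truth
#' contributions and cluster labels are returned in a separate table.
#'
#' @param spec a [population_spec()].
#' @param problem a [build_problem()] over the seven default sources (the
#'   archetypes reference those source names).
#' @param seed integer seed; defaults to `spec$seed`.
#' @return list with `samples` (data.frame) and `truth` (data.frame of true
#'   alpha vectors and cluster labels).
#' @export
generate_consumers <- function(spec, problem, seed = spec$seed) {
  set.seed(seed)
  n <- spec$n_humans
  arch <- .archetypes(problem$source_names)
  age_classes <- c("neonate", "infant", "young_juvenile", "old_juvenile",
                   "adolescent", "adult")
  age_probs <- c(0.04, 0.05, 0.05, 0.05, 0.06, 0.75)
  sites <- sample(names(spec$site_probs), n, TRUE, spec$site_probs)
  ages <- sample(age_classes, n, TRUE, age_probs)
  sexes <- sample(c("F", "M", "unknown"), n, TRUE, c(0.35, 0.45, 0.2))
  contexts <- sample(c("privileged_shaft", "second_church",
                       "ordinary_cemetery"), n, TRUE, c(0.45, 0.35, 0.2))
  cluster <- ifelse(runif(n) < spec$cluster1_prob, 1L, 2L)
  pnames <- vapply(problem$proxies, `[[`, character(1), "name")
  noise <- spec$proxy_noise_sd[pnames]
  noise[is.na(noise)] <- 0

  K <- length(problem$source_names)
  alphas <- matrix(NA_real_, n, K,
                   dimnames = list(NULL, problem$source_names))
  prox <- matrix(NA_real_, n, length(pnames),
                 dimnames = list(NULL, pnames))
  for (i in seq_len(n)) {
    t <- rbeta(1, 2, 2)
    al <- if (cluster[i] == 1L)
      (1 - t) * arch$c3_base + t * arch$c4_heavy
    else
      (1 - t) * arch$c3_base + t * arch$marine_heavy
    alphas[i, ] <- al
    mu <- forward_model(al, problem)
    prox[i, ] <- mu + rnorm(length(mu), 0, noise)
  }
  if (spec$nursing_offset != 0 && "d15N" %in% pnames) {
    nurse <- ages == "neonate"
    prox[nurse, "d15N"] <- prox[nurse, "d15N"] + spec$nursing_offset
  }

  qc_fail <- runif(n) < spec$qc_failure_rate
  cn <- runif(n, 3.1, 3.3)
  cn[qc_fail] <- runif(sum(qc_fail), 3.7, 4.5)
  samples <- data.frame(
    sample_id = sprintf("SH%03d", seq_len(n)),
    site = sites, species = "human",
    tissue = sample(c("bone", "tooth"), n, TRUE, c(0.9, 0.1)),
    element = "femur", age_class = ages, sex = sexes,
    burial_context = contexts,
    d13C_coll = if ("d13C_coll" %in% pnames) prox[, "d13C_coll"] else NA,
    d15N = if ("d15N" %in% pnames) prox[, "d15N"] else NA,
    cn_atomic = round(cn, 2),
    pct_C = round(runif(n, 38, 46), 1), pct_N = round(runif(n, 13, 17), 1),
    collagen_yield = round(runif(n, 1.5, 9), 1),
    d13C_carb = if ("d13C_carb" %in% pnames) prox[, "d13C_carb"] else NA,
    stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = samples$sample_id,
                      cluster = cluster, qc_fail = qc_fail,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(alphas, check.names = FALSE))
  list(samples = samples, truth = truth)
}

#' Simulate consumer targets from the mixing model's own generative process
#'
#' Draws one set of latent nuisance values (source signals, caloric
#' concentrations, diet-to-tissue offsets) from their priors — shared
#' across proxies — evaluates the forward model at `alpha`, and adds
#' Gaussian noise at each proxy's target sd. Rebuilding the problem with
#' the returned targets gives a synthetic inference problem whose true
#' contributions are `alpha`; over repeated draws with `alpha` itself
#' sampled from the uniform-simplex prior, posterior credible intervals
#' should attain nominal coverage.
#'
#' @param problem a [build_problem()] template (its targets are ignored).
#' @param alpha true contribution vector on the simplex.
#' @param seed integer seed.
#' @return named numeric vector of simulated proxy target means.
#' @export
simulate_targets <- function(problem, alpha, seed) {
  set.seed(seed)
  alpha <- .check_alpha(alpha, problem)
  srcs <- problem$sources
  K <- length(srcs)
  cp <- vapply(srcs, function(s)
    min(1, max(0, rnorm(1, s$concentration[["protein"]],
                        s$concentration_sd))), numeric(1))
  sig_draw <- list()
  for (k in seq_len(K)) for (f in .fractions)
    for (sg in names(srcs[[k]]$signals[[f]])) {
      v <- srcs[[k]]$signals[[f]][[sg]]
      sig_draw[[paste(k, f, sg)]] <- rnorm(1, v[1], v[2])
    }
  out <- numeric(length(problem$proxies))
  for (i in seq_along(problem$proxies)) {
    px <- problem$proxies[[i]]
    acc <- 0
    for (f in .fractions) {
      w <- px$routing[[f]]
      if (w == 0) next
      cf <- if (f == "protein") cp else 1 - cp
      sv <- vapply(seq_len(K), function(k)
        sig_draw[[paste(k, f, px$signal)]], numeric(1))
      acc <- acc + w * sum(alpha * cf * sv) / sum(alpha * cf)
    }
    off <- rnorm(1, px$offset_mean, px$offset_sd)
    out[i] <- off + acc + rnorm(1, 0, px$target_sd)
  }
  setNames(out, vapply(problem$proxies, `[[`, character(1), "name"))
}

#' Generate a synthetic resident/migrant mobility structure
#'
#' Draws water d18O values from a two-component Gaussian mixture (residents
#' and migrants) plus the planted outlier values, then back-converts every
#' water value through the inverse of the carbonate-to-water chain so that
#' the forward conversion applied by the pipeline reproduces the planted
#' water values exactly.
#'
#' @param spec a [population_spec()].
#' @param n number of mobility-assessed individuals including outliers;
#'   defaults to 66.
#' @param seed integer seed; defaults to `spec$seed`.
#' @return data.frame with `sample_id`, `origin_class` (resident, migrant,
#'   outlier), `d18O_water_true`, `d18O_carb_vpdb`.
#' @export
generate_mobility <- function(spec, n = 66, seed = spec$seed) {
  set.seed(seed)
  n_out <- length(spec$outlier_values)
  stopifnot(n > n_out)
  n_mix <- n - n_out
  n_res <- round(spec$resident_fraction * n_mix)
  n_mig <- n_mix - n_res
  water <- c(rnorm(n_res, spec$resident_mean, spec$resident_sd),
             rnorm(n_mig, spec$migrant_mean, spec$migrant_sd),
             spec$outlier_values)
  cls <- c(rep("resident", n_res), rep("migrant", n_mig),
           rep("outlier", n_out))
  data.frame(sample_id = sprintf("SM%03d", seq_len(n)),
             origin_class = cls,
             d18O_water_true = water,
             d18O_carb_vpdb = water_to_carbonate_vpdb(water),
             stringsAsFactors = FALSE)
}

#' Generate synthetic faunal baseline samples
#'
#' Site-specific collagen d13C baselines (slightly depleted at the forested
#' site), elevated and variable d15N reflecting manuring/penning, and water
#' d18O back-converted to carbonate.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return data.frame of faunal samples in the standard sample schema.
#' @export
generate_fauna <- function(spec, seed = spec$seed) {
  set.seed(seed + 1L)
  n <- spec$n_fauna
  if (n == 0) return(data.frame())
  species <- sample(c("pig", "sheep/goat", "cattle", "poultry", "horse",
                      "deer", "tortoise"), n, TRUE,
                    c(0.3, 0.3, 0.15, 0.1, 0.05, 0.05, 0.05))
  site <- sample(c("Tertiveri", "Montecorvino"), n, TRUE, c(0.55, 0.45))
  base_c <- ifelse(site == "Montecorvino", -21.9, -20.7)
  d13 <- rnorm(n, base_c, 1.0)
  d15 <- rnorm(n, 6.7, 1.6)
  water <- rnorm(n, -6.3, 2.0)
  data.frame(sample_id = sprintf("SF%03d", seq_len(n)),
             site = site, species = species,
             tissue = sample(c("bone", "tooth"), n, TRUE, c(0.8, 0.2)),
             element = "long bone", age_class = "adult", sex = "unknown",
             burial_context = "faunal_deposit",
             d13C_coll = round(d13, 2), d15N = round(d15, 2),
             cn_atomic = round(runif(n, 3.0, 3.4), 2),
             pct_C = round(runif(n, 38, 46), 1),
             pct_N = round(runif(n, 13, 17), 1),
             collagen_yield = round(runif(n, 1.5, 9), 1),
             d13C_carb = round(rnorm(n, -12.1, 1.5), 2),
             d18O_carb_vpdb = round(water_to_carbonate_vpdb(water), 3),
             stringsAsFactors = FALSE)
}

#' Generate isoscape calibration points from a known smooth field
#'
#' Samples `n` locations uniformly in the field's bounding box, evaluates
#' the true surface there and perturbs each value with Gaussian noise of
#' the stated standard error.
#'
#' @param field_spec list with `fun(lon, lat)` returning the true surface,
#'   `se` (per-point standard error), and `box`
#'   (`c(lon_min, lon_max, lat_min, lat_max)`).
#' @param n number of points.
#' @param seed integer seed.
#' @return data.frame with `lon`, `lat`, `mean`, `se`, `true`.
#' @export
generate_isoscape_points <- function(field_spec = default_field(), n = 200,
                                     seed = 1) {
  set.seed(seed)
  b <- field_spec$box
  lon <- runif(n, b[1], b[2])
  lat <- runif(n, b[3], b[4])
  tr <- field_spec$fun(lon, lat)
  data.frame(lon = lon, lat = lat,
             mean = tr + rnorm(n, 0, field_spec$se),
             se = field_spec$se, true = tr)
}

#' Default synthetic water-d18O field over southern/central Europe
#'
#' A smooth surface depleting northwards and gently varying with longitude,
#' qualitatively emulating the continental/latitudinal gradients of
#' precipitation-d18O models.
#'
#' @param se per-point standard error, per mil.
#' @return a field spec for [generate_isoscape_points()].
#' @export
default_field <- function(se = 0.3) {
  list(fun = function(lon, lat)
    -4.5 - 0.35 * (lat - 35) + 0.08 * (lon - 15) +
      0.6 * sin(lon / 6) * cos(lat / 5),
    se = se,
    box = c(lon_min = 5, lon_max = 25, lat_min = 36, lat_max = 50))
}

#' Write a complete synthetic fixture set to a directory
#'
#' Emits `samples.csv` (humans + fauna, with mobility carbonate values
#' attached to adult humans), `truth_diet.csv`, `truth_mobility.csv`,
#' `isoscape_points.csv` and `spec.json`.
#'
#' @param outdir output directory (created if absent).
#' @param spec a [population_spec()].
#' @param problem a [build_problem()]; defaults to the seven-source setup.
#' @param seed integer seed; defaults to `spec$seed`.
#' @return invisibly, the list of written paths.
#' @export
simulate_dataset <- function(outdir, spec = population_spec(),
                             problem = NULL, seed = spec$seed) {
  if (is.null(problem))
    problem <- build_problem(default_sources(), default_proxies())
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cons <- generate_consumers(spec, problem, seed)
  adults <- which(cons$samples$age_class == "adult")
  mob <- generate_mobility(spec, n = min(66, length(adults)),
                           seed = seed + 2L)
  cons$samples$d18O_carb_vpdb <- NA_real_
  idx <- adults[seq_len(nrow(mob))]
  cons$samples$d18O_carb_vpdb[idx] <- round(mob$d18O_carb_vpdb, 3)
  mob$sample_id <- cons$samples$sample_id[idx]
  fauna <- generate_fauna(spec, seed)
  samples <- rbind(cons$samples, fauna)
  iso <- generate_isoscape_points(default_field(), n = 200,
                                  seed = seed + 3L)
  paths <- list(
    samples = file.path(outdir, "samples.csv"),
    truth_diet = file.path(outdir, "truth_diet.csv"),
    truth_mobility = file.path(outdir, "truth_mobility.csv"),
    isoscape_points = file.path(outdir, "isoscape_points.csv"),
    spec = file.path(outdir, "spec.json"))
  write_samples(samples, paths$samples)
  write.csv(cons$truth, paths$truth_diet, row.names = FALSE)
  write.csv(mob, paths$truth_mobility, row.names = FALSE)
  write.csv(iso[c("lon", "lat", "mean", "se")], paths$isoscape_points,
            row.names = FALSE)
  jsonlite::write_json(unclass(spec)[setdiff(names(spec), "proxy_noise_sd")],
                       paths$spec, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
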