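# End-to-end orchestration: simulate -> qc -> convert -> cluster -> diet ->
# isoscape -> assign, driven by a single nested config (YAML/JSON or an R
# list). Every stochastic stage logs its seed in the run manifest and all
# outputs are digested, so a manifest plus the config reproduces a run.

.pipeline_stages <- c("simulate", "qc", "convert", "cluster_diet",
                      "cluster_oxygen", "diet", "isoscape", "assign")

#' Default pipeline configuration
#'
#' A complete configuration that simulates a synthetic assemblage and runs
#' every downstream stage on it. Use it as a template: any field can be
#' overridden, stages are skipped by setting them to `NULL` or
#' `enabled: false`.
#'
#' @param seed master seed for the run.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(enabled = TRUE),
    qc = list(cn_min = 2.9, cn_max = 3.6, min_yield = 1),
    convert = list(sigma = 2.0),
    cluster_diet = list(columns = c("d13C_coll", "d15N"), k_range = 1:5,
                        restarts = 20),
    cluster_oxygen = list(column = "d18O_water_vsmow", k = 2, trim = 0.05,
                          restarts = 20),
    diet = list(enabled = TRUE, chains = 4, iter = 25000, thin = 5,
                constraints = list(list(coef = c("C3 plants" = 1),
                                        rhs = 0.3, op = ">="))),
    isoscape = list(enabled = TRUE,
                    grid = list(lon_min = 5, lon_max = 25, lat_min = 36,
                                lat_max = 50, cell = 1),
                    site = c(lon = 15.1, lat = 41.5)),
    assign = list(sigma_individual = 2.0)
  )
}

.validate_config <- function(config) {
  problems <- character(0)
  need <- function(stage, fields) {
    st <- config[[stage]]
    if (is.null(st)) return()
    missing <- setdiff(fields, names(st))
    if (length(missing))
      problems <<- c(problems, sprintf("stage '%s' missing field(s): %s",
                                       stage, paste(missing, collapse = ", ")))
  }
  if (is.null(config$seed)) problems <- c(problems, "missing top-level seed")
  if (is.null(config$simulate) && is.null(config$input))
    problems <- c(problems,
                  "need either a 'simulate' stage or an 'input' samples path")
  need("qc", c("cn_min", "cn_max", "min_yield"))
  need("convert", "sigma")
  need("cluster_diet", "columns")
  need("cluster_oxygen", c("column", "k", "trim"))
  if (!is.null(config$diet) && isTRUE(config$diet$enabled)) {
    if (is.null(config$diet$sources) && is.null(config$diet$use_defaults))
      config$diet$use_defaults <- TRUE  # defaults are a documented fallback
  }
  if (length(problems))
    stop("invalid pipeline configuration:\n  ",
         paste(problems, collapse = "\n  "))
  invisible(TRUE)
}

.stage_enabled <- function(config, stage) {
  st <- config[[stage]]
  !is.null(st) && !isFALSE(st$enabled)
}

.digest_file <- function(path) unname(tools::md5sum(path))

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the full multi-proxy pipeline
#'
#' Executes the enabled stages in dependency order — simulate (or load),
#' quality control, carbonate-to-water conversion, dietary-proxy mixture
#' clustering, trimmed water-d18O clustering, Bayesian dietary mixing,
#' isoscape fitting and residence assignment — writing per-stage CSV/JSON
#' outputs and a run manifest with seeds and file digests.
#'
#' @param config configuration list (see [default_config()]) or a path to a
#'   YAML/JSON file.
#' @param outdir output directory.
#' @return the run manifest, invisibly; stage results as attribute
#'   `"results"`.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  if (is.character(config)) config <- read_config(config)
  .validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  manifest <- list(
    config_hash = .digest_string(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                  digits = NA, force = TRUE)),
    seed = seed, started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list())
  results <- list()
  t_stage <- function(expr) {
    t0 <- Sys.time()
    v <- force(expr)
    list(value = v, secs = as.numeric(difftime(Sys.time(), t0, "secs")))
  }
  record <- function(stage, paths, secs, extra = list()) {
    manifest$stages[[stage]] <<- c(list(
      seconds = round(secs, 2),
      outputs = lapply(paths, function(p)
        list(path = p, md5 = .digest_file(p)))), extra)
  }

  # --- input: simulate or load ------------------------------------------
  if (.stage_enabled(config, "simulate")) {
    st <- t_stage(simulate_dataset(file.path(outdir, "simulated"),
                                   spec = population_spec(seed = seed)))
    samples_path <- st$value$samples
    record("simulate", st$value, st$secs, list(seed = seed))
  } else samples_path <- config$input
  samples <- load_samples(samples_path)
  results$samples <- samples

  # --- qc ----------------------------------------------------------------
  qc <- qc_config(config$qc$cn_min, config$qc$cn_max, config$qc$min_yield)
  st <- t_stage(apply_qc(samples, qc))
  qcres <- st$value
  p_acc <- file.path(outdir, "accepted_samples.csv")
  p_rep <- file.path(outdir, "qc_report.json")
  write_samples(qcres$accepted, p_acc)
  write_qc_report(qcres$report, p_rep)
  record("qc", list(p_acc, p_rep), st$secs)
  results$qc <- qcres

  # --- convert -----------------------------------------------------------
  st <- t_stage(convert_samples_to_water(qcres$accepted,
                                         sigma = config$convert$sigma))
  conv <- st$value
  p_conv <- file.path(outdir, "converted_samples.csv")
  write_samples(conv, p_conv)
  record("convert", list(p_conv), st$secs)
  results$converted <- conv

  humans <- conv[tolower(conv$species) == "human" &
                   conv$age_class == "adult", , drop = FALSE]

  # --- dietary clustering ------------------------------------------------
  if (.stage_enabled(config, "cluster_diet")) {
    cols <- config$cluster_diet$columns
    xy <- humans[stats::complete.cases(humans[cols]), cols, drop = FALSE]
    st <- t_stage(fit_gmm_bic(xy,
                              k_range = config$cluster_diet$k_range %||% 1:5,
                              restarts = config$cluster_diet$restarts %||% 20,
                              seed = seed))
    p_cd <- file.path(outdir, "cluster_diet.json")
    .write_cluster_json(st$value, p_cd)
    record("cluster_diet", list(p_cd), st$secs, list(seed = seed))
    results$cluster_diet <- st$value
  }

  # --- oxygen clustering -------------------------------------------------
  if (.stage_enabled(config, "cluster_oxygen")) {
    col <- config$cluster_oxygen$column
    v <- humans[[col]]
    v <- v[!is.na(v)]
    st <- t_stage(fit_trimmed_1d(v, k = config$cluster_oxygen$k,
                                 trim_fraction = config$cluster_oxygen$trim,
                                 restarts = config$cluster_oxygen$restarts %||% 20,
                                 seed = seed))
    p_co <- file.path(outdir, "cluster_oxygen.json")
    .write_cluster_json(st$value, p_co)
    record("cluster_oxygen", list(p_co), st$secs, list(seed = seed))
    results$cluster_oxygen <- st$value
  }

  # --- diet mixing -------------------------------------------------------
  if (.stage_enabled(config, "diet")) {
    targets <- function(col) {
      x <- humans[[col]]; x <- x[!is.na(x)]
      c(mean(x), max(sd(x), 0.1))
    }
    problem <- build_problem(
      default_sources(),
      default_proxies(d13C_coll = targets("d13C_coll"),
                      d15N = targets("d15N"),
                      d13C_carb = targets("d13C_carb")),
      constraints = lapply(config$diet$constraints %||% list(), function(cn)
        mixing_constraint(unlist(cn$coef), cn$rhs, cn$op %||% ">=")))
    st <- t_stage(sample_posterior(problem,
                                   chains = config$diet$chains %||% 4,
                                   iter = config$diet$iter %||% 4000,
                                   thin = config$diet$thin %||% 2,
                                   seed = seed))
    post <- st$value
    p_draws <- file.path(outdir, "diet_draws.csv")
    write.csv(as.data.frame(post$draws), p_draws, row.names = FALSE)
    p_sum <- file.path(outdir, "diet_summary.json")
    smry <- summarize_posterior(post)
    jsonlite::write_json(list(sources = smry$sources,
                              macronutrients = smry$macronutrients,
                              diagnostics = post$diagnostics),
                         p_sum, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    record("diet", list(p_draws, p_sum), st$secs,
           list(seed = seed, converged = isTRUE(attr(post, "converged"))))
    results$diet <- post
  }

  # --- isoscape + assignment --------------------------------------------
  if (.stage_enabled(config, "isoscape")) {
    gs <- config$isoscape$grid
    grid <- grid_spec(gs$lon_min, gs$lon_max, gs$lat_min, gs$lat_max,
                      gs$cell)
    pts_path <- config$isoscape$points %||%
      file.path(outdir, "simulated", "isoscape_points.csv")
    pts <- read.csv(pts_path)
    st <- t_stage(fit_isoscape(pts, grid, seed = seed))
    iso <- st$value
    p_iso <- file.path(outdir, "isoscape.csv")
    write.csv(as_long_table(iso), p_iso, row.names = FALSE)
    record("isoscape", list(p_iso), st$secs, list(seed = seed))
    results$isoscape <- iso
    if (!is.null(config$isoscape$site)) {
      results$local <- local_estimate(iso, config$isoscape$site[["lon"]],
                                      config$isoscape$site[["lat"]])
    }
    if (.stage_enabled(config, "assign") &&
        !is.null(results$cluster_oxygen)) {
      sol <- results$cluster_oxygen
      maps <- list()
      for (j in seq_len(sol$k)) {
        semean <- sqrt(sol$variances[j] / max(sum(sol$assignments == j,
                                                  na.rm = TRUE), 1))
        maps[[paste0("cluster_", j)]] <-
          assign_residence(iso, sol$means[j], max(semean, 0.1))
      }
      v <- humans[[config$cluster_oxygen$column]]
      for (i in sol$outliers) {
        vi <- v[!is.na(humans[[config$cluster_oxygen$column]])][i]
        maps[[paste0("outlier_", i)]] <-
          assign_residence(iso, vi, config$assign$sigma_individual %||% 2)
      }
      p_maps <- character(0)
      for (nm in names(maps)) {
        p <- file.path(outdir, sprintf("residence_%s.csv", nm))
        write.csv(as_long_table(maps[[nm]]), p, row.names = FALSE)
        p_maps <- c(p_maps, p)
      }
      record("assign", as.list(p_maps), 0)
      results$residence <- maps
    }
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  p_man <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  attr(manifest, "results") <- results
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.digest_string <- function(s) {
  f <- tempfile()
  writeLines(as.character(s), f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

.write_cluster_json <- function(sol, path) {
  out <- list(k = sol$k, covariance_family = sol$covariance_family,
              weights = sol$weights,
              means = if (is.matrix(sol$means)) apply(sol$means, 1, c,
                                                      simplify = FALSE)
                      else sol$means,
              n_outliers = sol$n_outliers, outliers = sol$outliers,
              assignments = sol$assignments,
              loglik = sol$loglik, bic = sol$bic, seed = sol$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
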