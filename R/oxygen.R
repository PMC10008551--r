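# Affine coefficients of the carbonate -> phosphate -> drinking-water chain.
# VPDB->VSMOW is the standard scale conversion; carbonate->phosphate follows
# the Chenery regression; phosphate->water the Pollard regression.
.oxy_chain <- list(
  vpdb_to_vsmow  = c(slope = 1.03092, intercept = 30.92),
  carb_to_phos   = c(slope = 1.0322,  intercept = -9.6849),
  phos_to_water  = c(slope = 1.55,    intercept = -33.49)
)

.oxy_scales <- c("carbonate_VPDB", "carbonate_VSMOW", "phosphate_VSMOW",
                 "water_VSMOW")

#' A scale-tagged oxygen isotope value
#'
#' Tags a numeric vector of per-mil values with the scale it is expressed on
#' so that conversions can refuse inputs on the wrong scale, plus an
#' attached 1-sigma uncertainty.
#'
#' @param value numeric vector, per mil.
#' @param scale one of `"carbonate_VPDB"`, `"carbonate_VSMOW"`,
#'   `"phosphate_VSMOW"`, `"water_VSMOW"`.
#' @param sigma non-negative uncertainty, per mil (scalar or vector).
#' @return an `oxygen_value` object.
#' @export
oxygen_value <- function(value, scale, sigma = 0) {
  scale <- match.arg(scale, .oxy_scales)
  stopifnot(all(sigma >= 0))
  structure(list(value = as.numeric(value), scale = scale,
                 sigma = rep_len(as.numeric(sigma), length(value))),
            class = "oxygen_value")
}

#' @export
print.oxygen_value <- function(x, ...) {
  cat(sprintf("d18O [%s]: %s\n", x$scale,
              paste(sprintf("%.2f±%.2f", x$value, x$sigma), collapse = ", ")))
  invisible(x)
}

.oxy_check <- function(x, expected) {
  if (inherits(x, "oxygen_value")) {
    if (x$scale != expected)
      stop(sprintf("input is on scale '%s'; expected '%s'", x$scale, expected))
    x$value
  } else as.numeric(x)
}

.oxy_wrap <- function(x, value, scale) {
  if (inherits(x, "oxygen_value")) oxygen_value(value, scale, x$sigma)
  else value
}

#' Re-express carbonate d18O from the VPDB to the VSMOW scale
#'
#' `d18O_VSMOW = 1.03092 * d18O_VPDB + 30.92`.
#'
#' @param x numeric per-mil values on VPDB, or an [oxygen_value()] with
#'   scale `carbonate_VPDB`.
#' @return same type as `x`, on the carbonate VSMOW scale.
#' @export
vpdb_to_vsmow <- function(x) {
  v <- .oxy_check(x, "carbonate_VPDB")
  k <- .oxy_chain$vpdb_to_vsmow
  .oxy_wrap(x, k[["slope"]] * v + k[["intercept"]], "carbonate_VSMOW")
}

#' Convert carbonate d18O (VSMOW) to phosphate d18O (VSMOW)
#'
#' `d18O_phosphate = 1.0322 * d18O_carbonate - 9.6849`.
#'
#' @param x numeric per-mil values, or an [oxygen_value()] with scale
#'   `carbonate_VSMOW`.
#' @return same type as `x`, phosphate VSMOW.
#' @export
carbonate_to_phosphate <- function(x) {
  v <- .oxy_check(x, "carbonate_VSMOW")
  k <- .oxy_chain$carb_to_phos
  .oxy_wrap(x, k[["slope"]] * v + k[["intercept"]], "phosphate_VSMOW")
}

#' Convert phosphate d18O (VSMOW) to drinking-water d18O (VSMOW)
#'
#' `d18O_water = 1.55 * d18O_phosphate - 33.49`.
#'
#' @param x numeric per-mil values, or an [oxygen_value()] with scale
#'   `phosphate_VSMOW`.
#' @return same type as `x`, water VSMOW.
#' @export
phosphate_to_water <- function(x) {
  v <- .oxy_check(x, "phosphate_VSMOW")
  k <- .oxy_chain$phos_to_water
  .oxy_wrap(x, k[["slope"]] * v + k[["intercept"]], "water_VSMOW")
}

#' Full chain: bioapatite carbonate d18O (VPDB) to ingested-water d18O
#'
#' Composes the three affine maps and attaches a conservative per-sample
#' uncertainty (default 2 per mil) reflecting cooking, brewing, diagenesis
#' and regression error. Values are kept at full precision; round only at
#' report time.
#'
#' @param x numeric carbonate d18O on VPDB, per mil.
#' @param sigma_out uncertainty to attach to the water values, per mil.
#' @return an [oxygen_value()] on the water VSMOW scale.
#' @export
#' @examples
#' carbonate_vpdb_to_water(c(-6.9, -1.6))  # approx -10.4 and -1.7
carbonate_vpdb_to_water <- function(x, sigma_out = 2.0) {
  v <- .oxy_check(x, "carbonate_VPDB")
  w <- phosphate_to_water(carbonate_to_phosphate(vpdb_to_vsmow(v)))
  oxygen_value(w, "water_VSMOW", sigma_out)
}

#' Invert the chain: water d18O (VSMOW) back to carbonate d18O (VPDB)
#'
#' Exact algebraic inverse of [carbonate_vpdb_to_water()]; used by the
#' synthetic-data generators so planted water values survive the forward
#' conversion unchanged.
#'
#' @param x numeric water d18O (VSMOW), or an [oxygen_value()] on that scale.
#' @return numeric carbonate d18O on VPDB.
#' @export
water_to_carbonate_vpdb <- function(x) {
  v <- .oxy_check(x, "water_VSMOW")
  k3 <- .oxy_chain$phos_to_water
  k2 <- .oxy_chain$carb_to_phos
  k1 <- .oxy_chain$vpdb_to_vsmow
  phos <- (v - k3[["intercept"]]) / k3[["slope"]]
  vsmow <- (phos - k2[["intercept"]]) / k2[["slope"]]
  unname((vsmow - k1[["intercept"]]) / k1[["slope"]])
}

#' Add drinking-water d18O columns to a sample table
#'
#' Applies the conversion chain to `d18O_carb_vpdb` for rows whose carbonate
#' passed quality control (when a `carbonate_ok` column is present), writing
#' `d18O_water_vsmow` and `d18O_water_sigma` columns.
#'
#' @param samples data.frame with a `d18O_carb_vpdb` column.
#' @param sigma uncertainty attached to each converted value, per mil.
#' @return the data.frame with the two water columns appended.
#' @export
convert_samples_to_water <- function(samples, sigma = 2.0) {
  stopifnot("d18O_carb_vpdb" %in% names(samples))
  ok <- if ("carbonate_ok" %in% names(samples)) samples$carbonate_ok
        else !is.na(samples$d18O_carb_vpdb)
  ok <- ok & !is.na(samples$d18O_carb_vpdb)
  w <- rep(NA_real_, nrow(samples))
  w[ok] <- carbonate_vpdb_to_water(samples$d18O_carb_vpdb[ok])$value
  samples$d18O_water_vsmow <- w
  samples$d18O_water_sigma <- ifelse(ok, sigma, NA_real_)
  samples
}
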