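#' @useDynLib palaeomix, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aggregate complete.cases cor dist dnorm kmeans mad median
#'   optim pnorm pwilcox quantile rbeta rbinom rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv
"_PACKAGE"

# Columns holding per-mil (or %) measurements; everything else in an input
# table is carried through untouched as metadata.
.numeric_cols <- c(
  "d13C_coll", "d15N", "cn_atomic", "pct_C", "pct_N", "collagen_yield",
  "d13C_carb", "d18O_carb_vpdb"
)

.isotope_cols <- c("d13C_coll", "d15N", "cn_atomic", "pct_C", "pct_N",
                   "collagen_yield", "d13C_carb", "d18O_carb_vpdb")

#' Parse numbers that may use the Unicode minus sign
#'
#' Mass-spectrometry exports and spreadsheet round-trips often emit U+2212
#' instead of the ASCII hyphen-minus. Blank cells become `NA`.
#'
#' @param x character vector.
#' @return numeric vector; an attribute-free `NA` for blanks.
#' @keywords internal
parse_permil <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  x <- gsub("−", "-", x)
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  attr(out, "bad") <- which(bad)
  out
}

#' Load isotope samples from a delimited table
#'
#' Reads a UTF-8 comma-delimited table with one row per specimen. The header
#' must contain `sample_id`; the measurement columns (`d13C_coll`, `d15N`,
#' `cn_atomic`, `pct_C`, `pct_N`, `collagen_yield`, `d13C_carb`,
#' `d18O_carb_vpdb`) are parsed as numbers when present, accepting both the
#' ASCII hyphen and the Unicode minus sign; any other column is preserved
#' verbatim as metadata. Blank cells become missing values.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` of samples, one row per specimen.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,site,d13C_coll", "TC1,Tertiveri,-19.0"), f)
#' load_samples(f)
load_samples <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character", fileEncoding = "UTF-8")
  if (!"sample_id" %in% names(df))
    stop("input table must contain a 'sample_id' column")
  df$sample_id <- trimws(df$sample_id)
  if (any(!nzchar(df$sample_id)))
    stop("empty sample_id in row(s): ",
         paste(which(!nzchar(df$sample_id)), collapse = ", "))
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicate sample_id(s): ", paste(dup, collapse = ", "))
  for (cl in intersect(.numeric_cols, names(df))) {
    v <- parse_permil(df[[cl]])
    bad <- attr(v, "bad")
    if (length(bad))
      stop(sprintf("unparseable numeric value in column '%s', row %d: '%s'",
                   cl, bad[1], df[[cl]][bad[1]]))
    attr(v, "bad") <- NULL
    df[[cl]] <- v
  }
  df
}

#' Write samples back to CSV (ASCII minus, empty cell for missing)
#'
#' @param samples data.frame of samples.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  write.csv(samples, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Collagen quality-control configuration
#'
#' The atomic C/N acceptance window defaults to the 2.9--3.6 convention for
#' well-preserved bone collagen; the minimum collagen yield defaults to 1%
#' by weight. Both are configurable.
#'
#' @param cn_min,cn_max acceptance bounds for the atomic C/N ratio.
#' @param min_yield minimum collagen yield, percent by weight.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(cn_min = 2.9, cn_max = 3.6, min_yield = 1) {
  stopifnot(cn_min > 0, cn_max > cn_min, min_yield >= 0)
  structure(list(cn_min = cn_min, cn_max = cn_max, min_yield = min_yield),
            class = "qc_config")
}

#' Assess collagen and carbonate quality for one sample
#'
#' Collagen passes when an atomic C/N ratio is present and inside the
#' acceptance window and the collagen yield (when recorded) meets the
#' minimum. Carbonate values of a sample whose collagen failed are excluded
#' too, since poor collagen preservation flags diagenetic alteration of the
#' whole specimen; a sample without a carbonate measurement gets
#' `carbonate_ok = FALSE` with a `missing_measurement` reason only.
#'
#' @param sample one-row data.frame (or list) with the sample's fields.
#' @param qc a [qc_config()].
#' @return list with `collagen_ok`, `carbonate_ok`, `reasons` (character).
#' @export
assess_collagen_quality <- function(sample, qc = qc_config()) {
  getv <- function(f) {
    v <- sample[[f]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v[1])
  }
  cn <- getv("cn_atomic")
  yield <- getv("collagen_yield")
  carb <- getv("d13C_carb")
  o18 <- getv("d18O_carb_vpdb")
  has_carb <- !is.na(carb) || !is.na(o18)

  reasons <- character(0)
  collagen_ok <- TRUE
  if (is.na(cn)) {
    collagen_ok <- FALSE
    reasons <- c(reasons, "missing_measurement")
  } else if (cn < qc$cn_min || cn > qc$cn_max) {
    collagen_ok <- FALSE
    reasons <- c(reasons, "cn_out_of_range")
  }
  if (!is.na(yield) && yield < qc$min_yield) {
    collagen_ok <- FALSE
    reasons <- c(reasons, "insufficient_collagen")
  }

  if (collagen_ok && has_carb) {
    carbonate_ok <- TRUE
  } else if (!collagen_ok && has_carb) {
    carbonate_ok <- FALSE
    reasons <- c(reasons, "collagen_failed_so_carbonate_excluded")
  } else {
    carbonate_ok <- FALSE
    reasons <- c(reasons, "missing_measurement")
  }
  list(collagen_ok = collagen_ok, carbonate_ok = carbonate_ok,
       reasons = unique(reasons))
}

#' Apply quality control to a sample table
#'
#' Screens every sample with [assess_collagen_quality()], appends
#' `collagen_ok` / `carbonate_ok` flag columns, and reports exclusion counts
#' and percentages per species group (human vs fauna). Samples whose
#' collagen failed are dropped from the accepted set entirely, so their
#' carbonate values can never propagate into downstream summaries.
#'
#' @param samples data.frame from [load_samples()].
#' @param qc a [qc_config()].
#' @return list with `accepted` (flagged data.frame of passing samples),
#'   `flagged` (all samples with flags), and `report` (per-group counts,
#'   percentages rounded to 1 decimal, and per-sample reasons).
#' @export
apply_qc <- function(samples, qc = qc_config()) {
  n <- nrow(samples)
  flags <- lapply(seq_len(n), function(i)
    assess_collagen_quality(samples[i, , drop = FALSE], qc))
  samples$collagen_ok <- vapply(flags, `[[`, logical(1), "collagen_ok")
  samples$carbonate_ok <- vapply(flags, `[[`, logical(1), "carbonate_ok")
  species <- if ("species" %in% names(samples)) samples$species
             else rep("unknown", n)
  group <- ifelse(tolower(species) == "human", "human", "fauna")

  per_group <- lapply(unique(group), function(g) {
    idx <- group == g
    n_tot <- sum(idx)
    n_exc <- sum(!samples$collagen_ok[idx])
    list(group = g, n_total = n_tot, n_excluded = n_exc,
         percent_excluded = round(100 * n_exc / n_tot, 1))
  })
  names(per_group) <- vapply(per_group, `[[`, character(1), "group")

  reasons <- lapply(flags, `[[`, "reasons")
  names(reasons) <- samples$sample_id
  report <- list(
    groups = per_group,
    n_total = n,
    n_excluded = sum(!samples$collagen_ok),
    reasons = reasons[!samples$collagen_ok]
  )
  list(accepted = samples[samples$collagen_ok, , drop = FALSE],
       flagged = samples, report = report)
}

#' Write a QC report as JSON
#' @param report the `report` element of [apply_qc()]'s result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Per-group summary statistics for isotope proxies
#'
#' Mean, sample standard deviation (n-1 denominator), min, max and the count
#' of non-missing values, for each proxy within each group. Missing values
#' are skipped per proxy; the sd is reported only when at least two values
#' are present. Groups are ordered deterministically by their key, so the
#' result is invariant to row order.
#'
#' @param samples data.frame of samples.
#' @param grouping character vector of grouping column names (may be empty
#'   for a grand summary).
#' @param proxies character vector of numeric proxy columns.
#' @return data.frame with one row per group x proxy.
#' @export
summarize_groups <- function(samples,
                             grouping = "site",
                             proxies = c("d13C_coll", "d15N")) {
  stopifnot(all(proxies %in% names(samples)))
  if (nrow(samples) == 0) return(data.frame())
  key <- if (length(grouping)) {
    interaction(samples[grouping], drop = TRUE, sep = "\r")
  } else factor(rep("all", nrow(samples)))
  levs <- sort(levels(key))
  rows <- list()
  for (lv in levs) {
    idx <- key == lv
    keyvals <- strsplit(lv, "\r", fixed = TRUE)[[1]]
    for (p in proxies) {
      v <- samples[[p]][idx]
      v <- v[!is.na(v)]
      if (!length(v)) next
      row <- as.list(setNames(keyvals, if (length(grouping)) grouping
                              else "group"))
      row$proxy <- p
      row$n <- length(v)
      row$mean <- mean(v)
      row$sd <- if (length(v) >= 2) sd(v) else NA_real_
      row$min <- min(v)
      row$max <- max(v)
      rows[[length(rows) + 1L]] <- as.data.frame(row,
                                                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test with the min(U1, U2) convention
#'
#' U1 counts pairs where a value from `a` is below one from `b`, with half
#' a count for ties (midranks); U is the smaller of U1 and its mirror U2 =
#' n1*n2 - U1. When there are no ties and n1*n2 <= 10000 the two-sided p is
#' computed from the exact null distribution of U; otherwise a tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return list with `U`, `U1`, `U2`, `n1`, `n2`, `p_two_sided`, `method`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  r <- rank(c(a, b))
  # Rank-sum identity: U1 (pairs with a < b, ties half) from b's rank sum.
  rb <- sum(r[(n1 + 1):(n1 + n2)])
  u1 <- rb - n2 * (n2 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= 10000) {
    p <- min(1, 2 * pwilcox(u, n1, n2))
    method <- "exact_enumeration"
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n1 + n2 + 1 - tie_term))
    z <- (u - mu + 0.5) / sigma  # continuity-corrected, u <= mu by construction
    p <- min(1, 2 * pnorm(z))
    method <- "normal_approx_tie_corrected"
  }
  list(U = u, U1 = u1, U2 = u2, n1 = n1, n2 = n2,
       p_two_sided = p, method = method)
}
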