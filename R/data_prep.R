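#' Read a long-format catch table
#'
#' Reads and validates the monthly survey export. Columns are matched by
#' name, so column order is irrelevant. Rows that cannot enter the
#' analysis (unparseable year/month, non-positive effort, negative count,
#' unknown station, unknown gear or age class) are rejected individually
#' with a logged reason; a missing required column or an empty file is an
#' error.
#'
#' @param path CSV with columns `station_id`, `year`, `month`, `gear`
#'   (`midwater`/`otter`), `age_class` (`age0`/`age1plus`), `count`,
#'   `effort` (m^3 for midwater, m^2 for otter).
#' @param station_metadata_path CSV with `station_id`, `region`,
#'   `lateral_habitat`; station ids in the catch table must resolve here.
#' @return Data frame of validated records with region and lateral habitat
#'   joined in; rejected rows (with reasons) are attached as
#'   `attr(, "rejected")`.
#' @export
read_catch_table <- function(path, station_metadata_path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("catch table is empty: ", path)
  need <- c("station_id", "year", "month", "gear", "age_class", "count",
            "effort")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("catch table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  st <- utils::read.csv(station_metadata_path, stringsAsFactors = FALSE)
  if (!all(c("station_id", "region", "lateral_habitat") %in% names(st)))
    stop("station metadata needs station_id, region, lateral_habitat")

  d <- raw[need]
  for (col in c("year", "month", "count", "effort"))
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))

  reason <- rep(NA_character_, nrow(d))
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why
  flag(is.na(d$year) | is.na(d$month) | d$month %% 1 != 0 |
         d$month < 1 | d$month > 12, "unparseable date")
  flag(!d$gear %in% c("midwater", "otter"), "unknown gear")
  flag(!d$age_class %in% c("age0", "age1plus"), "unknown age class")
  flag(is.na(d$effort) | d$effort <= 0, "non-positive effort")
  flag(is.na(d$count) | d$count < 0, "negative or missing count")
  flag(!d$station_id %in% st$station_id, "unknown station")

  rejected <- cbind(row = which(!is.na(reason)),
                    d[!is.na(reason), , drop = FALSE],
                    reason = reason[!is.na(reason)])
  ok <- d[is.na(reason), , drop = FALSE]
  out <- merge(ok, st[, c("station_id", "region", "lateral_habitat")],
               by = "station_id", sort = FALSE)
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Read a freshwater-outflow series
#'
#' Accepts either a daily table (`date`, `outflow`) or a monthly table
#' (`year`, `month`, `outflow`), in cfs, and returns monthly means. Rows
#' with non-positive outflow are rejected with a logged reason.
#'
#' @param path CSV path.
#' @return Data frame `year`, `month`, `outflow` (monthly mean cfs), with
#'   rejected rows attached as `attr(, "rejected")`.
#' @export
read_flow <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("flow table is empty: ", path)
  if ("date" %in% names(d)) {
    dt <- as.Date(d$date)
    d$year <- as.integer(format(dt, "%Y"))
    d$month <- as.integer(format(dt, "%m"))
  }
  if (!all(c("year", "month", "outflow") %in% names(d)))
    stop("flow table needs (date, outflow) or (year, month, outflow)")
  d$outflow <- suppressWarnings(as.numeric(d$outflow))
  bad <- is.na(d$year) | is.na(d$month) | is.na(d$outflow) | d$outflow <= 0
  rejected <- d[bad, , drop = FALSE]
  d <- d[!bad, , drop = FALSE]
  agg <- stats::aggregate(outflow ~ year + month, d, mean)
  agg <- agg[order(agg$year, agg$month), c("year", "month", "outflow")]
  rownames(agg) <- NULL
  attr(agg, "rejected") <- rejected
  agg
}

#' Catch per unit effort
#'
#' `count / effort`: fish per cubic metre of water sampled (midwater
#' trawl) or per square metre swept (otter trawl). Vectorized.
#'
#' @param count non-negative catch count.
#' @param effort positive effort.
#' @return CPUE, same length as the inputs.
#' @export
compute_cpue <- function(count, effort) {
  if (any(is.na(effort)) || any(effort <= 0)) stop("effort must be positive")
  if (any(is.na(count)) || any(count < 0)) stop("count must be non-negative")
  count / effort
}

#' Monthly CPUE matrix for one gear and age class
#'
#' Arranges CPUE as a series-by-month matrix (one row per station) on a
#' strictly increasing, contiguous monthly axis spanning the observed
#' range; months without a record are `NA`, never omitted.
#'
#' @param catch validated catch records (see [read_catch_table()]).
#' @param gear,age_class the series subset to extract.
#' @return Matrix with station ids as row names and `"YYYY-MM"` column
#'   names.
#' @export
build_cpue_matrix <- function(catch, gear, age_class) {
  d <- catch[catch$gear == gear & catch$age_class == age_class, ]
  if (nrow(d) == 0L) stop("no records for ", gear, "/", age_class)
  d$cpue <- compute_cpue(d$count, d$effort)
  yr <- range(d$year)
  months <- expand.grid(month = 1:12, year = yr[1]:yr[2])
  key <- sprintf("%d-%02d", months$year, months$month)
  stations <- sort(unique(d$station_id))
  m <- matrix(NA_real_, length(stations), length(key),
              dimnames = list(stations, key))
  m[cbind(match(d$station_id, stations),
          match(sprintf("%d-%02d", d$year, d$month), key))] <- d$cpue
  m
}

#' Series completeness
#'
#' Fraction of non-missing cells per series (row).
#'
#' @param mat series-by-time matrix.
#' @return Named numeric vector in `[0, 1]`.
#' @export
completeness <- function(mat) rowMeans(!is.na(mat))

#' Filter series by completeness
#'
#' Keeps series whose fraction of non-missing cells is at least
#' `threshold` (inclusive, so a series at exactly the threshold is
#' retained). Dropped series are listed in `attr(, "dropped")`.
#'
#' @param mat series-by-time matrix.
#' @param threshold completeness threshold in `(0, 1]`, default 0.5.
#' @return The retained rows of `mat`.
#' @export
filter_by_completeness <- function(mat, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  comp <- completeness(mat)
  keep <- comp >= threshold
  if (!any(keep)) warning("no series meets the completeness threshold")
  out <- mat[keep, , drop = FALSE]
  attr(out, "dropped") <- data.frame(series = rownames(mat)[!keep],
                                     completeness = unname(comp[!keep]))
  out
}

#' Natural-log transform with a series-level zero offset
#'
#' `ln(x + delta)` with `delta` half the smallest positive value within
#' the series (so zero catches map to a value just below the smallest
#' observed positive CPUE). A series with no positive values gets
#' `delta = 1`.
#'
#' @param mat series-by-time CPUE matrix (raw scale).
#' @param delta offset; `NULL` (default) computes it per series.
#' @return Log-scale matrix; the offsets used are in `attr(, "delta")`.
#' @export
log_cpue_matrix <- function(mat, delta = NULL) {
  if (is.null(delta)) {
    delta <- apply(mat, 1L, function(x) {
      pos <- x[!is.na(x) & x > 0]
      if (length(pos)) min(pos) / 2 else 1
    })
  } else delta <- rep(delta, length.out = nrow(mat))
  out <- log(mat + delta)
  attr(out, "delta") <- delta
  out
}

#' Replace within-series outliers by neighbour interpolation
#'
#' Flags values at least `sd_multiplier` sample SDs from the series mean
#' (moments computed over the whole series in a single pass, outliers
#' included) and replaces each by linear interpolation between the nearest
#' non-missing, non-outlier neighbours; at the series boundary the single
#' available neighbour is used. Missing values are untouched. Intended for
#' log-scale monthly series.
#'
#' @param x numeric vector (log scale; `NA` = missing).
#' @param sd_multiplier outlier threshold in SD units, default 2.
#' @return `x` with outliers replaced; the number of replacements in
#'   `attr(, "replacements")` and their positions in `attr(, "outliers")`.
#' @export
clean_series <- function(x, sd_multiplier = 2) {
  obs <- which(!is.na(x))
  if (length(obs) < 3L) {
    warning("fewer than 3 non-missing values: series returned unchanged")
    attr(x, "replacements") <- 0L
    attr(x, "outliers") <- integer(0)
    return(x)
  }
  mu <- mean(x[obs]); s <- stats::sd(x[obs])
  out_idx <- obs[abs(x[obs] - mu) >= sd_multiplier * s]
  good <- setdiff(obs, out_idx)
  for (i in out_idx) {
    lo <- good[good < i]; hi <- good[good > i]
    lo <- if (length(lo)) max(lo) else NA_integer_
    hi <- if (length(hi)) min(hi) else NA_integer_
    x[i] <- if (is.na(lo) && is.na(hi)) x[i]
            else if (is.na(lo)) x[hi]
            else if (is.na(hi)) x[lo]
            else x[lo] + (x[hi] - x[lo]) * (i - lo) / (hi - lo)
  }
  attr(x, "replacements") <- length(out_idx)
  attr(x, "outliers") <- out_idx
  x
}

#' Clean every series of a matrix
#'
#' Applies [clean_series()] row-wise.
#'
#' @inheritParams clean_series
#' @param mat series-by-time matrix (log scale).
#' @return Cleaned matrix; per-series replacement counts in
#'   `attr(, "replacements")`.
#' @export
clean_matrix <- function(mat, sd_multiplier = 2) {
  reps <- integer(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    ci <- clean_series(mat[i, ], sd_multiplier)
    reps[i] <- attr(ci, "replacements")
    mat[i, ] <- ci
  }
  names(reps) <- rownames(mat)
  attr(mat, "replacements") <- reps
  mat
}

#' Aggregate monthly series to annual window means
#'
#' For each year, averages the non-missing values within the seasonal
#' month window (May-October for young-of-the-year, February-May for
#' age-1+, January-June for the flow covariate). A year with fewer than
#' `min_frac` of its window months observed is set missing rather than
#' letting one or two months masquerade as an annual mean.
#'
#' @param mat series-by-month matrix with `"YYYY-MM"` column names.
#' @param month_window non-empty subset of 1:12.
#' @param min_frac minimum observed fraction of window months, default
#'   0.5.
#' @return Series-by-year matrix with years as column names.
#' @export
aggregate_annual <- function(mat, month_window, min_frac = 0.5) {
  if (length(month_window) == 0L) stop("month window is empty")
  stopifnot(all(month_window %in% 1:12))
  parts <- strsplit(colnames(mat), "-", fixed = TRUE)
  yr <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  mo <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  if (anyNA(yr) || anyNA(mo)) stop("column names must be YYYY-MM")
  years <- sort(unique(yr))
  sel <- mo %in% month_window
  out <- matrix(NA_real_, nrow(mat), length(years),
                dimnames = list(rownames(mat), years))
  for (j in seq_along(years)) {
    cols <- which(sel & yr == years[j])
    block <- mat[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(block))
    vals <- rowMeans(block, na.rm = TRUE)
    vals[n_obs < min_frac * length(month_window)] <- NA_real_
    out[, j] <- vals
  }
  out
}

#' Annual flow covariate
#'
#' Window mean of monthly outflow per year (January-June by default, the
#' window holding most of the annual outflow), via [aggregate_annual()].
#'
#' @param flow monthly flow table (`year`, `month`, `outflow`), e.g. from
#'   [read_flow()].
#' @param months month window, default 1:6.
#' @param years optional year range to cover (defaults to the observed
#'   range).
#' @return Named numeric vector of annual window means (cfs).
#' @export
annual_flow <- function(flow, months = 1:6, years = NULL) {
  if (is.null(years)) years <- min(flow$year):max(flow$year)
  key <- sprintf("%d-%02d", rep(years, each = 12L), rep(1:12, length(years)))
  m <- matrix(NA_real_, 1L, length(key), dimnames = list("flow", key))
  idx <- match(sprintf("%d-%02d", flow$year, flow$month), key)
  m[1L, idx[!is.na(idx)]] <- flow$outflow[!is.na(idx)]
  out <- aggregate_annual(m, months)
  stats::setNames(as.numeric(out), colnames(out))
}

#' Standardize an annual flow series
#'
#' Natural-log transform then z-score, so covariate effects are per SD of
#' log flow; `log = FALSE` z-scores the raw series.
#'
#' @param x annual flow values (positive when `log = TRUE`).
#' @param log log-transform first? Default `TRUE`.
#' @return Standardized series (mean 0, SD 1).
#' @export
standardize_flow <- function(x, log = TRUE) {
  if (log) {
    if (any(x <= 0, na.rm = TRUE)) stop("flow must be positive on the log scale")
    x <- base::log(x)
  }
  s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) stop("flow series is constant")
  as.numeric((x - mean(x, na.rm = TRUE)) / s)
}

#' Month windows for the annual age-class aggregation
#' @param age_class `"age0"` or `"age1plus"`.
#' @return Integer month window.
#' @export
age_month_window <- function(age_class) {
  switch(age_class, age0 = 5:10, age1plus = 2:5,
         stop("unknown age class: ", age_class))
}

#' Full CPUE preprocessing pipeline
#'
#' Runs the cleaning protocol for one gear and age class: CPUE, monthly
#' matrix, completeness filter (default at one half, inclusive), log
#' transform with per-series zero offset, 2-SD outlier interpolation, and
#' seasonal-window annual aggregation. Missing values are left missing for
#' the state-space likelihood, never interpolated.
#'
#' @param catch validated catch records.
#' @param stations station metadata (`station_id`, `region`,
#'   `lateral_habitat`); used to label the retained series.
#' @param gear,age_class series subset.
#' @param completeness_threshold minimum monthly completeness, default 0.5.
#' @param sd_multiplier outlier threshold, default 2.
#' @param delta log offset (`NULL`: per-series half-minimum rule).
#' @return List: `annual` (series x year log-CPUE), `monthly` (cleaned
#'   monthly log matrix), `labels` (retained series with habitat
#'   attributes), `report` (dropped series, per-series replacement counts,
#'   offsets).
#' @export
prepare_annual_cpue <- function(catch, stations, gear, age_class,
                                completeness_threshold = 0.5,
                                sd_multiplier = 2, delta = NULL) {
  cm <- build_cpue_matrix(catch, gear, age_class)
  cm <- filter_by_completeness(cm, completeness_threshold)
  dropped <- attr(cm, "dropped")
  lg <- log_cpue_matrix(cm, delta)
  cl <- clean_matrix(lg, sd_multiplier)
  annual <- aggregate_annual(cl, age_month_window(age_class))
  idx <- match(rownames(annual), stations$station_id)
  if (anyNA(idx)) stop("retained series with station id missing from metadata")
  labels <- data.frame(
    series_id = paste(rownames(annual), gear, sep = "."),
    station_id = rownames(annual),
    region = stations$region[idx],
    lateral_habitat = stations$lateral_habitat[idx],
    gear = gear, age_class = age_class)
  rownames(annual) <- labels$series_id
  list(annual = annual, monthly = cl, labels = labels,
       report = list(dropped = dropped,
                     replacements = attr(cl, "replacements"),
                     delta = attr(lg, "delta")))
}
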