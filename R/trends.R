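#' Theil-Sen trend estimate with Mann-Kendall significance
#'
#' Robust trend: the median of all pairwise slopes
#' `(y_j - y_i) / (t_j - t_i)`, `i < j`. Significance comes from the
#' Mann-Kendall test, i.e. Kendall's tau between value and time
#' (via [stats::cor.test()]).
#'
#' @param y numeric series (`NA` allowed).
#' @param t time points, default `seq_along(y)`.
#' @return List: `slope`, `intercept` (median residual), `p_value`, `n`.
#' @export
theil_sen <- function(y, t = seq_along(y)) {
  ok <- !is.na(y) & !is.na(t)
  y <- y[ok]; t <- t[ok]
  n <- length(y)
  if (n < 3L) stop("Theil-Sen needs at least 3 non-missing points")
  dy <- outer(y, y, `-`); dt <- outer(t, t, `-`)
  slopes <- dy[lower.tri(dy)] / dt[lower.tri(dt)]
  slope <- stats::median(slopes)
  mk <- suppressWarnings(stats::cor.test(t, y, method = "kendall"))
  list(slope = slope, intercept = stats::median(y - slope * t),
       p_value = mk$p.value, n = n)
}

#' Coefficient of variation in percent
#'
#' `100 * sd / |mean|` with the sample SD. Undefined (returned as `NA`
#' with a warning) when the mean is zero.
#'
#' @param x numeric series (`NA` dropped).
#' @return CV in percent.
#' @export
cv_percent <- function(x) {
  x <- x[!is.na(x)]
  mu <- mean(x)
  if (mu == 0) {
    warning("zero mean: CV undefined")
    return(NA_real_)
  }
  100 * stats::sd(x) / abs(mu)
}

#' Per-series trend and variability summary
#'
#' Theil-Sen slope and Mann-Kendall p-value on the series as given
#' (typically annual log-CPUE) and the coefficient of variation on a
#' configurable scale (default: back-transformed to the response scale
#' with `exp`, since CV of a log series has no natural interpretation).
#'
#' @param mat series-by-year matrix.
#' @param labels data frame aligned with the rows of `mat` (habitat-group
#'   attributes are carried through).
#' @param cv_transform function applied before computing the CV, default
#'   [exp]; use [identity] for the raw scale.
#' @return Data frame: one row per series with `slope`, `p_value`,
#'   `cv_percent`, `n`, plus the label columns.
#' @export
trend_summary <- function(mat, labels = NULL, cv_transform = exp) {
  years <- as.numeric(colnames(mat))
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    ts <- theil_sen(mat[i, ], years)
    data.frame(series_id = rownames(mat)[i], slope = ts$slope,
               p_value = ts$p_value, cv_percent = cv_percent(cv_transform(mat[i, ])),
               n = ts$n)
  })
  out <- do.call(rbind, rows)
  if (!is.null(labels)) out <- cbind(out, labels[match(out$series_id,
                                                       labels$series_id),
                                                 setdiff(names(labels),
                                                         "series_id"),
                                                 drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Group-wise and pooled trend-vs-variability regressions
#'
#' Ordinary least squares of CV on Theil-Sen slope within each habitat
#' group, a pooled line across all series, and the share of series with
#' negative (and significantly negative/positive) trends.
#'
#' @param summary a [trend_summary()] data frame.
#' @param group name of the grouping column, default `"group"`.
#' @param min_n groups with fewer series are omitted with a note, default
#'   3.
#' @param alpha significance cutoff for the trend shares, default 0.05.
#' @return List: `groups` (per-group slope/intercept/R^2/n), `pooled`,
#'   `shares` (fractions of negative, significant-negative and
#'   significant-positive trends), `omitted`.
#' @export
trend_cv_regression <- function(summary, group = "group", min_n = 3L,
                                alpha = 0.05) {
  if (is.null(summary[[group]])) stop("no grouping column '", group, "'")
  ols <- function(d) {
    f <- stats::lm(cv_percent ~ slope, data = d)
    data.frame(slope = stats::coef(f)[["slope"]],
               intercept = stats::coef(f)[["(Intercept)"]],
               r_squared = summary(f)$r.squared, n = nrow(d))
  }
  gs <- split(summary, summary[[group]])
  small <- names(gs)[vapply(gs, nrow, integer(1)) < min_n]
  gs <- gs[setdiff(names(gs), small)]
  groups <- do.call(rbind, lapply(names(gs), function(g)
    cbind(group = g, ols(gs[[g]]))))
  rownames(groups) <- NULL
  neg <- summary$slope < 0
  sig <- summary$p_value < alpha
  list(groups = groups, pooled = ols(summary),
       shares = c(negative = mean(neg),
                  significant_negative = mean(neg & sig),
                  significant_positive = mean(!neg & sig)),
       omitted = small)
}

#' Fall-survey style annual abundance index
#'
#' Weighted regional means of catch per tow summed over September-December:
#' `index_y = sum_{m=9..12} sum_r w_r * mean_catch_r(m, y)`. A year
#' missing any of the four index months is flagged partial.
#'
#' @param monthly_regional data frame `year`, `month`, `region`, `value`
#'   (mean catch per tow).
#' @param weights named vector of area weighting factors per region
#'   (unpublished for this survey; defaults to 1 for every region).
#' @return Data frame `year`, `index`, `partial`.
#' @export
fmwt_style_index <- function(monthly_regional, weights = NULL) {
  d <- monthly_regional[monthly_regional$month %in% 9:12, ]
  regions <- sort(unique(d$region))
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(regions)),
                                                   regions)
  if (!all(regions %in% names(weights)))
    stop("weights missing for region(s): ",
         paste(setdiff(regions, names(weights)), collapse = ", "))
  d$w <- weights[d$region]
  monthly <- stats::aggregate(cbind(contrib = w * value) ~ year + month, d, sum)
  out <- do.call(rbind, lapply(split(monthly, monthly$year), function(b)
    data.frame(year = b$year[1], index = sum(b$contrib),
               partial = length(unique(b$month)) < 4L)))
  rownames(out) <- NULL
  out
}

#' Period-wise index-vs-flow regressions
#'
#' Simple linear regressions of the (transformed) abundance index on the
#' (transformed) annual flow within prespecified ecosystem periods:
#' before the non-native clam invasion (through 1987), between the clam
#' invasion and the pelagic collapse (1988-2002), and after it
#' (2003 onward), by default. Both variables are log10-transformed by
#' default, matching the axes these relationships are usually displayed
#' on.
#'
#' @param index data frame `year`, `index`.
#' @param flow named annual flow vector (names = years) or data frame
#'   `year`, `flow`.
#' @param breaks upper year of each period but the last, default
#'   `c(1987, 2002)`.
#' @param transform `"log10"` (default) or `"raw"`.
#' @param min_n periods with fewer years are omitted with a note.
#' @return Data frame per period: `period`, `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`; omitted periods in `attr(, "omitted")`.
#' @export
period_regressions <- function(index, flow, breaks = c(1987, 2002),
                               transform = c("log10", "raw"), min_n = 3L) {
  transform <- match.arg(transform)
  if (is.data.frame(flow)) flow <- stats::setNames(flow$flow, flow$year)
  d <- data.frame(year = index$year, index = index$index,
                  flow = as.numeric(flow[as.character(index$year)]))
  d <- d[stats::complete.cases(d), ]
  if (transform == "log10") {
    d <- d[d$index > 0 & d$flow > 0, ]
    d$index <- log10(d$index); d$flow <- log10(d$flow)
  }
  breaks <- sort(breaks)
  labs <- if (identical(breaks, c(1987, 2002)))
    c("pre_clam", "pre_pod", "post_pod")
  else paste0("period", seq_len(length(breaks) + 1L))
  d$period <- labs[findInterval(d$year, breaks + 1L) + 1L]
  rows <- list(); omitted <- character(0)
  for (p in labs) {
    dp <- d[d$period == p, ]
    if (nrow(dp) < min_n) { omitted <- c(omitted, p); next }
    f <- stats::lm(index ~ flow, data = dp)
    sf <- summary(f)
    rows[[p]] <- data.frame(period = p, slope = stats::coef(f)[["flow"]],
                            intercept = stats::coef(f)[["(Intercept)"]],
                            r_squared = sf$r.squared,
                            p_value = sf$coefficients["flow", "Pr(>|t|)"],
                            n = nrow(dp))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  out
}
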