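#' Summarize a time-varying slope path
#'
#' Reduces a DLM slope trajectory to the quantities a time-averaged model
#' can be compared against: the time-average of the slope, its maximum and
#' minimum with their pointwise intervals, and whether the upper interval
#' of the maximum and the lower interval of the minimum bound the
#' time-averaged slope (they must, for pointwise intervals around a path
#' whose mean lies between its extremes; the flag records it explicitly).
#'
#' @param slope slope path (non-empty numeric).
#' @param lower,upper pointwise interval bounds (optional; `NA` allowed).
#' @return List: `mean`, `max`, `max_lower`, `max_upper`, `argmax`,
#'   `min`, `min_lower`, `min_upper`, `argmin`, `bounded`, `has_ci`.
#' @export
summarize_dlm_slopes <- function(slope, lower = NULL, upper = NULL) {
  ok <- !is.na(slope)
  if (!any(ok)) stop("slope path is empty")
  s <- slope[ok]
  i_max <- which.max(slope); i_min <- which.min(slope)
  has_ci <- !is.null(lower) && !is.null(upper) &&
    !is.na(lower[i_min]) && !is.na(upper[i_max])
  if (!has_ci) lower <- upper <- rep(NA_real_, length(slope))
  out <- list(mean = mean(s),
              max = slope[i_max], max_lower = lower[i_max],
              max_upper = upper[i_max], argmax = i_max,
              min = slope[i_min], min_lower = lower[i_min],
              min_upper = upper[i_min], argmin = i_min,
              has_ci = has_ci)
  out$bounded <- if (has_ci) out$min_lower <= out$mean &&
    out$mean <= out$max_upper else NA
  out
}

#' Compare time-averaged and time-varying flow effects
#'
#' Builds one comparison row per habitat group: the covariate effect from
#' the time-averaged (MARSS) fit with its Wald interval, against the DLM
#' slope summarized over time. Flags whether the two point estimates share
#' a sign and whether the MARSS interval overlaps the DLM slope envelope
#' (bounded by the upper interval of the maximum slope and the lower
#' interval of the minimum slope, the envelope these comparisons are
#' plotted with).
#'
#' @param marss_effects the `$effects` data frame from
#'   [fit_flow_effect()] (`state`, `estimate`, `lower`, `upper`).
#' @param dlm a [fit_dlm()] result on the same groups.
#' @param variant optional label (e.g. `"age0_contemporary"`) carried into
#'   the table.
#' @return Data frame, one row per group: MARSS estimate and interval,
#'   DLM mean/max/min slopes with intervals, `same_sign`, `ci_overlap`.
#' @export
effect_comparison <- function(marss_effects, dlm, variant = NA_character_) {
  stopifnot(inherits(dlm, "dlm_fit"))
  groups <- dlm$design$groups
  if (!setequal(groups, marss_effects$state))
    stop("MARSS effects and DLM groups do not match")
  rows <- lapply(groups, function(g) {
    me <- marss_effects[marss_effects$state == g, ]
    sm <- summarize_dlm_slopes(dlm$slope[g, ], dlm$slope_lower[g, ],
                               dlm$slope_upper[g, ])
    data.frame(
      variant = variant, group = g,
      marss = me$estimate, marss_lower = me$lower, marss_upper = me$upper,
      dlm_mean = sm$mean,
      dlm_max = sm$max, dlm_max_upper = sm$max_upper,
      dlm_min = sm$min, dlm_min_lower = sm$min_lower,
      same_sign = sign(me$estimate) == sign(sm$mean),
      ci_overlap = if (is.na(me$lower) || !sm$has_ci) NA else
        me$lower <= sm$max_upper && me$upper >= sm$min_lower)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sign agreement between modelling approaches
#'
#' Fraction of comparison rows whose time-averaged (MARSS) effect and
#' time-averaged DLM slope have the same sign. An exact zero is its own
#' sign class, so a zero effect never agrees with a nonzero one. Rows
#' missing either point estimate are excluded and counted.
#'
#' @param comparison an [effect_comparison()] table (or any data frame
#'   with `marss` and `dlm_mean` columns).
#' @return List: `fraction` (agreeing share of usable rows), `n_same`,
#'   `n_used`, `n_excluded`, and the per-row logical `table`.
#' @export
sign_agreement <- function(comparison) {
  est1 <- comparison$marss; est2 <- comparison$dlm_mean
  usable <- !is.na(est1) & !is.na(est2)
  same <- sign(est1[usable]) == sign(est2[usable])
  id_cols <- intersect(c("variant", "group"), names(comparison))
  list(fraction = mean(same), n_same = sum(same), n_used = sum(usable),
       n_excluded = sum(!usable),
       table = data.frame(comparison[usable, id_cols, drop = FALSE],
                          same_sign = same))
}
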