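#' Competing spatial-structure hypotheses
#'
#' The six candidate population structures examined with time-invariant
#' multivariate state-space (MARSS) models. Each hypothesis groups the
#' observed station-gear series into latent population states via a
#' one-hot `Z` matrix: a single estuary-wide state (H1), vertical-habitat
#' states by gear (H2: otter vs. midwater trawl, i.e. benthic vs. pelagic),
#' region states (H3), region-by-gear states (H4), lateral-habitat states
#' (H5: channel vs. shoal), and lateral-by-vertical habitat states (H6).
#'
#' @return Data frame with columns `hypothesis`, `description`, `n_states`
#'   (for a fully crossed station design spanning 3 regions, both lateral
#'   habitats and both gears).
#' @export
hypothesis_table <- function() {
  data.frame(
    hypothesis = paste0("H", 1:6),
    description = c(
      "Estuary-wide: one state",
      "Vertical habitat: gear-specific states (otter / midwater)",
      "Region: Central Bay / San Pablo Bay / Suisun-Confluence",
      "Vertical habitat x region",
      "Lateral habitat: channel / shoal",
      "Lateral x vertical habitat (channel/shoal x midwater/otter)"),
    n_states = c(1L, 2L, 3L, 6L, 2L, 4L)
  )
}

hypothesis_grouping <- function(labels, hypothesis) {
  need <- switch(hypothesis,
                 H1 = character(0),
                 H2 = "gear",
                 H3 = "region",
                 H4 = c("region", "gear"),
                 H5 = "lateral_habitat",
                 H6 = c("lateral_habitat", "gear"),
                 stop("unknown hypothesis: ", hypothesis))
  for (col in need) {
    if (is.null(labels[[col]]) || anyNA(labels[[col]]))
      stop("series labels lack the '", col, "' attribute required by ",
           hypothesis)
  }
  if (length(need) == 0L) return(rep("estuary", nrow(labels)))
  do.call(paste, c(lapply(need, function(col) as.character(labels[[col]])),
                   sep = "."))
}

#' Build the Z matrix for a spatial hypothesis
#'
#' Maps each observed series (a station-gear combination carrying `region`,
#' `lateral_habitat` and `gear` labels) to exactly one latent state under
#' the chosen hypothesis, as a one-hot `p x m` matrix.
#'
#' @param labels data frame with one row per observed series and columns
#'   `series_id`, `region`, `lateral_habitat`, `gear` (whichever the
#'   hypothesis needs must be present and non-missing).
#' @param hypothesis one of `"H1"`..`"H6"` (see [hypothesis_table()]).
#' @return One-hot matrix with series in rows and states (named by group)
#'   in columns.
#' @export
build_hypothesis_Z <- function(labels, hypothesis) {
  grp <- factor(hypothesis_grouping(labels, hypothesis))
  Z <- outer(grp, levels(grp), `==`) * 1
  rownames(Z) <- if (!is.null(labels$series_id)) as.character(labels$series_id)
  colnames(Z) <- levels(grp)
  Z
}

#' Compare spatial hypotheses by AICc
#'
#' Fits one covariate-free state-space model per hypothesis (process
#' variances diagonal and unequal across states; observation variances
#' shared within region-by-gear groups by default) and ranks the fits by
#' small-sample corrected AIC. Ties in AICc are broken in favour of fewer
#' parameters. Non-converged fits are flagged, not dropped.
#'
#' @param y `p x T` matrix of annual log-CPUE (series in rows; `NA` =
#'   missing).
#' @param labels series label data frame (see [build_hypothesis_Z()]).
#' @param hypotheses character vector of hypothesis ids to compare.
#' @param R_sharing `"region_gear"` (default: one observation variance per
#'   region-by-gear group) or `"series"` (one per series).
#' @param method,control passed to [fit_ml()].
#' @return Data frame ranked by AICc with columns `hypothesis`,
#'   `n_states`, `k`, `loglik`, `AICc`, `dAICc`, `converged`; the fitted
#'   models are attached as `attr(, "fits")`.
#' @export
compare_hypotheses <- function(y, labels,
                               hypotheses = paste0("H", 1:6),
                               R_sharing = c("region_gear", "series"),
                               method = "em",
                               control = list(em_tol = 1e-5, em_maxit = 2000L)) {
  R_sharing <- match.arg(R_sharing)
  if (length(hypotheses) < 2L) stop("need at least two hypotheses to compare")
  Rg <- make_R_groups(labels, R_sharing)
  fits <- lapply(hypotheses, function(h) {
    Z <- build_hypothesis_Z(labels, h)
    spec <- ssm_spec(Z, T = ncol(y), R_groups = Rg)
    fit_ml(spec, y, method = method, control = control)
  })
  names(fits) <- hypotheses
  tab <- data.frame(
    hypothesis = hypotheses,
    n_states = vapply(fits, function(f) f$spec$m, integer(1)),
    k = vapply(fits, function(f) f$k, integer(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    AICc = vapply(fits, function(f) f$AICc, numeric(1)),
    converged = vapply(fits, function(f) isTRUE(f$convergence$converged),
                       logical(1)),
    row.names = NULL)
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab <- tab[order(tab$AICc, tab$k), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

make_R_groups <- function(labels, R_sharing) {
  if (R_sharing == "series") return(seq_len(nrow(labels)))
  if (is.null(labels$region) || is.null(labels$gear))
    stop("region_gear R sharing needs 'region' and 'gear' label columns")
  as.integer(factor(paste(labels$region, labels$gear, sep = ".")))
}

#' Time-averaged flow effect from a covariate MARSS model
#'
#' Refits the winning spatial structure with an annual flow covariate in
#' the state equation and reports the per-state covariate effect (the `C`
#' matrix) with Wald confidence intervals. The covariate should be the
#' standardized annual flow from [standardize_flow()], so effects are per
#' standard deviation of log flow.
#'
#' @inheritParams compare_hypotheses
#' @param hypothesis spatial structure to use (default the lateral-by-
#'   vertical habitat structure `"H6"`).
#' @param covariate numeric covariate of length `T` (standardized annual
#'   flow); must not be constant.
#' @param conf_level confidence level for the Wald intervals.
#' @return List with the `ssm_fit` (`$fit`) and `$effects`, a data frame
#'   per state: `state`, `estimate`, `lower`, `upper`, `sign`,
#'   `excludes_zero`.
#' @export
fit_flow_effect <- function(y, labels, covariate, hypothesis = "H6",
                            R_sharing = c("region_gear", "series"),
                            method = "bfgs", control = list(),
                            conf_level = 0.95) {
  R_sharing <- match.arg(R_sharing)
  covariate <- as.numeric(covariate)
  if (length(covariate) != ncol(y))
    stop("covariate length must equal the number of modelled years")
  if (stats::sd(covariate) == 0)
    stop("covariate is constant: the flow effect is unidentifiable")
  Z <- build_hypothesis_Z(labels, hypothesis)
  spec <- ssm_spec(Z, T = ncol(y), R_groups = make_R_groups(labels, R_sharing),
                   covariates = matrix(covariate, 1L), C = "free")
  fit <- fit_ml(spec, y, method = method, control = control)
  ci <- param_confint(fit, level = conf_level)
  ci <- ci[ci$block == "C", ]
  eff <- data.frame(
    state = colnames(Z),
    estimate = as.numeric(fit$params$C),
    lower = ci$lower, upper = ci$upper,
    row.names = NULL)
  eff$sign <- sign(eff$estimate)
  eff$excludes_zero <- !is.na(eff$lower) & (eff$lower > 0 | eff$upper < 0)
  list(fit = fit, effects = eff)
}

#' Extract smoothed population states
#'
#' Returns the observation-error-free state trajectories (smoothed means
#' and standard errors) of a fitted model, labelled by habitat group.
#'
#' @param fit an [fit_ml()] result.
#' @return List with `mean` and `se`, both `m x T` matrices with state
#'   names as row names. A warning is attached when the fit did not
#'   converge.
#' @export
extract_states <- function(fit) {
  stopifnot(inherits(fit, "ssm_fit"))
  if (!isTRUE(fit$convergence$converged))
    warning("extracting states from a non-converged fit")
  list(mean = fit$states$mean, se = fit$states$se)
}
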