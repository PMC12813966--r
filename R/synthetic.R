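#' Define a synthetic monitoring scenario
#'
#' A scenario bundles everything the generators need to emulate a
#' multi-decade, multi-station estuarine trawl survey: the station design,
#' the true spatial structure of the population (one of the H1-H6
#' hypotheses), true process/observation variances and flow effects, the
#' flow model, and the data-quality knobs (station-level missingness,
#' outlier rate). All generators are seed-deterministic: the same scenario
#' and seed give byte-identical output.
#'
#' The default values reproduce the bundled "survey-like" study design:
#' 25 stations sampled by two gears over 41 years (1980-2020), a
#' four-state lateral-by-vertical habitat truth (H6) with process variance
#' 0.2 and observation variance 0.3 per series, and a flow effect of
#' (0.5, 0, 0.25, 0) across the four habitat groups.
#'
#' @param seed integer seed.
#' @param n_stations number of stations (regions and lateral habitats are
#'   assigned in a fixed balanced rotation).
#' @param gears gear types; each station is sampled by every gear.
#' @param years modelled years.
#' @param hypothesis true grouping structure, `"H1"`..`"H6"`.
#' @param Q,R true process and observation variances (recycled to length).
#' @param C true per-state flow effects (length = number of states under
#'   `hypothesis`), or `NULL` for no flow forcing.
#' @param x0 true initial states (default 0).
#' @param flow_phi AR(1) coefficient of annual log flow.
#' @param flow_meanlog,flow_sdlog level and innovation scale of log flow
#'   (cfs), tuned to Delta-outflow-like magnitudes.
#' @param missingness per-station probability that a monthly (or annual)
#'   cell is missing; scalar or vector of length `n_stations`.
#' @param outlier_rate fraction of non-missing monthly cells receiving an
#'   injected catch spike.
#' @param exact_missingness when `TRUE` the monthly-catch generator masks
#'   an exact (rounded) fraction of each series rather than Bernoulli
#'   cells, so a station's realized completeness equals the design value —
#'   used for fixtures that probe the completeness filter at its boundary.
#' @param age_classes age classes emitted by the monthly catch generator.
#' @param sigma_month within-year (monthly) log-CPUE noise SD.
#' @return An object of class `flow_scenario`.
#' @export
flow_scenario <- function(seed = 1L, n_stations = 25L,
                          gears = c("midwater", "otter"),
                          years = 1980:2020, hypothesis = "H6",
                          Q = 0.2, R = 0.3, C = c(0.5, 0, 0.25, 0),
                          x0 = 0, flow_phi = 0.3,
                          flow_meanlog = log(3e4), flow_sdlog = 0.5,
                          missingness = 0, outlier_rate = 0,
                          age_classes = c("age0", "age1plus"),
                          sigma_month = 0.7, exact_missingness = FALSE) {
  stopifnot(n_stations >= 1L, length(years) >= 2L,
            all(missingness >= 0), all(missingness < 1),
            outlier_rate >= 0, outlier_rate < 1, all(Q >= 0), all(R >= 0))
  if (length(missingness) == 1L) missingness <- rep(missingness, n_stations)
  if (length(missingness) != n_stations)
    stop("missingness must be scalar or one value per station")
  structure(list(
    seed = as.integer(seed), n_stations = as.integer(n_stations),
    gears = gears, years = years, T = length(years),
    hypothesis = hypothesis, Q = Q, R = R, C = C, x0 = x0,
    flow_phi = flow_phi, flow_meanlog = flow_meanlog,
    flow_sdlog = flow_sdlog, missingness = missingness,
    outlier_rate = outlier_rate, age_classes = age_classes,
    sigma_month = sigma_month, exact_missingness = exact_missingness
  ), class = "flow_scenario")
}

#' Bundled survey-like scenario
#'
#' The default end-to-end scenario: 35 candidate stations of which 10 are
#' low-quality (monthly completeness below one half, so the completeness
#' filter drops them and 25 survive, as in a realistic long-term survey),
#' H6 truth, `Q = 0.2`, `R = 0.3`, flow effects `(0.5, 0, 0.25, 0)`, and a
#' 3% outlier rate.
#'
#' @param seed integer seed.
#' @return A [flow_scenario()].
#' @export
survey_scenario <- function(seed = 1L) {
  miss <- c(rep(0.15, 25), rep(0.6, 10))
  flow_scenario(seed = seed, n_stations = 35L, missingness = miss,
                outlier_rate = 0.03)
}

#' Station design for a scenario
#'
#' Deterministic balanced assignment of stations to the three regions and
#' the two lateral habitats.
#'
#' @param scenario a [flow_scenario()].
#' @return Data frame with `station_id`, `region`, `lateral_habitat`.
#' @export
station_metadata <- function(scenario) {
  n <- scenario$n_stations
  regions <- c("central_bay", "san_pablo_bay", "suisun_confluence")
  data.frame(
    station_id = sprintf("S%02d", seq_len(n)),
    region = regions[(seq_len(n) - 1L) %% 3L + 1L],
    lateral_habitat = c("channel", "shoal")[(seq_len(n) - 1L) %/% 3L %% 2L + 1L]
  )
}

series_labels <- function(scenario, age_class = "age0") {
  st <- station_metadata(scenario)
  g <- expand.grid(station_id = st$station_id, gear = scenario$gears,
                   stringsAsFactors = FALSE)
  out <- merge(g, st, by = "station_id", sort = FALSE)
  out <- out[order(out$gear, out$station_id), ]
  out$age_class <- age_class
  out$series_id <- paste(out$station_id, out$gear, sep = ".")
  rownames(out) <- NULL
  out[, c("series_id", "station_id", "region", "lateral_habitat", "gear",
          "age_class")]
}

#' Simulate a monthly freshwater-outflow series
#'
#' Log outflow follows an AR(1) annual level (persistence `flow_phi`) with
#' a wet-season cycle (winter-spring high, as in a Mediterranean-climate
#' estuary) plus monthly noise, exponentiated to cfs.
#'
#' @param scenario a [flow_scenario()].
#' @param seed optional seed override.
#' @return Data frame with `year`, `month`, `outflow` (cfs).
#' @export
simulate_flow <- function(scenario, seed = scenario$seed) {
  set.seed(seed)
  T <- scenario$T
  z <- numeric(T)
  z[1] <- stats::rnorm(1, 0, scenario$flow_sdlog)
  for (t in seq_len(T - 1L))
    z[t + 1L] <- scenario$flow_phi * z[t] +
      stats::rnorm(1, 0, scenario$flow_sdlog * sqrt(1 - scenario$flow_phi^2))
  seasonal <- 0.9 * cos(2 * pi * (1:12 - 2.5) / 12)  # peak late winter
  out <- expand.grid(month = 1:12, year = scenario$years)
  out$outflow <- exp(scenario$flow_meanlog + z[match(out$year, scenario$years)] +
                       seasonal[out$month] + stats::rnorm(nrow(out), 0, 0.15))
  out[, c("year", "month", "outflow")]
}

# annual Jan-Jun standardized log-flow covariate from a monthly flow table
flow_covariate_from_monthly <- function(flow, years) {
  sub <- flow[flow$month %in% 1:6 & flow$year %in% years, ]
  ann <- tapply(sub$outflow, factor(sub$year, levels = years), mean)
  standardize_flow(as.numeric(ann))
}

#' Simulate annual multivariate state-space data
#'
#' Forward-simulates the population model: latent habitat-group states
#' follow `x_t = x_{t-1} + C c_t + w_t` and each station-gear series
#' observes its group's state with independent noise,
#' `y_t = Z x_t + v_t`. Cells are masked missing-completely-at-random per
#' station. The flow covariate is the standardized annual January-June
#' mean of a simulated monthly flow series.
#'
#' @param scenario a [flow_scenario()].
#' @param seed optional seed override.
#' @param age_class label attached to the generated series.
#' @return List: `y` (`p x T`), `labels`, `Z`, `states` (true `m x T`),
#'   `covariate` (standardized annual flow), `flow` (monthly table), and
#'   `truth` (the generating parameters).
#' @export
simulate_ssm <- function(scenario, seed = scenario$seed, age_class = "age0") {
  flow <- simulate_flow(scenario, seed = seed)
  set.seed(seed + 1L)
  labels <- series_labels(scenario, age_class)
  Z <- build_hypothesis_Z(labels, scenario$hypothesis)
  m <- ncol(Z); p <- nrow(Z); T <- scenario$T
  Q <- rep(scenario$Q, length.out = m)
  R <- rep(scenario$R, length.out = p)
  x0 <- rep(scenario$x0, length.out = m)
  cc <- if (is.null(scenario$C)) rep(0, T) else flow_covariate_from_monthly(flow, scenario$years)
  C <- if (is.null(scenario$C)) rep(0, m) else rep(scenario$C, length.out = m)

  x <- matrix(0, m, T)
  prev <- x0
  for (t in seq_len(T)) {
    x[, t] <- prev + C * cc[t] + stats::rnorm(m, 0, sqrt(Q))
    prev <- x[, t]
  }
  rownames(x) <- colnames(Z)
  y <- Z %*% x + matrix(stats::rnorm(p * T, 0, sqrt(R)), p, T)
  miss_p <- scenario$missingness[match(labels$station_id,
                                       station_metadata(scenario)$station_id)]
  mask <- matrix(stats::runif(p * T), p, T) < miss_p
  y[mask] <- NA
  dimnames(y) <- list(labels$series_id, scenario$years)

  list(y = y, labels = labels, Z = Z, states = x,
       covariate = if (is.null(scenario$C)) NULL else cc, flow = flow,
       truth = list(Q = Q, R = R, C = C, x0 = x0, missing = mask))
}

#' Simulate a monthly catch table
#'
#' Emulates the raw survey export that enters the preprocessing pipeline:
#' monthly counts per station, gear and age class, with effort (volume for
#' the midwater trawl, area swept for the otter trawl). Monthly log-CPUE is
#' the sum of a gear-specific base level, the station's habitat-group
#' latent state (an H-structure random walk forced by flow as in
#' [simulate_ssm()]), a seasonal presence profile for the age class, and
#' monthly noise. Injected outliers shift a cell by 5-8 within-series SDs
#' (an order-of-magnitude catch spike, the kind of anomaly the 2-SD
#' cleaning rule is meant to absorb); the truth record lists every injected
#' outlier and masked cell so recovery can be scored.
#'
#' @param scenario a [flow_scenario()].
#' @param seed optional seed override.
#' @return List: `catch` (long data frame: `station_id`, `year`, `month`,
#'   `gear`, `age_class`, `count`, `effort`), `stations`, `flow` (monthly
#'   table), and `truth` (outlier/missing cell tables, latent states,
#'   covariate).
#' @export
simulate_monthly_catch <- function(scenario, seed = scenario$seed) {
  flow <- simulate_flow(scenario, seed = seed)
  set.seed(seed + 2L)
  st <- station_metadata(scenario)
  years <- scenario$years; T <- scenario$T
  cc <- flow_covariate_from_monthly(flow, years)

  # latent habitat-group states shared by both age classes
  lab0 <- series_labels(scenario, "age0")
  Zg <- build_hypothesis_Z(lab0, scenario$hypothesis)
  m <- ncol(Zg)
  Q <- rep(scenario$Q, length.out = m)
  C <- if (is.null(scenario$C)) rep(0, m) else rep(scenario$C, length.out = m)
  x <- matrix(0, m, T)
  prev <- rep(scenario$x0, length.out = m)
  for (t in seq_len(T)) {
    x[, t] <- prev + C * cc[t] + stats::rnorm(m, 0, sqrt(Q))
    prev <- x[, t]
  }
  rownames(x) <- colnames(Zg)

  base_log_cpue <- c(midwater = -4.8, otter = -4.1)
  windows <- list(age0 = 5:10, age1plus = 2:5)
  grid <- expand.grid(station_id = st$station_id, gear = scenario$gears,
                      age_class = scenario$age_classes, year = years,
                      month = 1:12, stringsAsFactors = FALSE)
  grid <- merge(grid, st, by = "station_id", sort = FALSE)
  grp <- hypothesis_grouping(
    data.frame(region = grid$region, lateral_habitat = grid$lateral_habitat,
               gear = grid$gear), scenario$hypothesis)
  state_val <- x[cbind(match(grp, rownames(x)), match(grid$year, years))]
  in_window <- mapply(function(a, mo) mo %in% windows[[a]],
                      grid$age_class, grid$month)
  mu <- base_log_cpue[grid$gear] + state_val + ifelse(in_window, 0, -1.5)

  n <- nrow(grid)
  sigma <- scenario$sigma_month
  log_cpue <- mu + stats::rnorm(n, 0, sigma)
  outlier <- stats::runif(n) < scenario$outlier_rate
  log_cpue[outlier] <- log_cpue[outlier] +
    stats::runif(sum(outlier), 5, 8) * sigma
  effort <- ifelse(grid$gear == "midwater",
                   stats::rnorm(n, 6000, 400), stats::rnorm(n, 3000, 200))
  effort <- pmax(effort, 500)
  count <- round(exp(log_cpue) * effort)

  miss_p <- scenario$missingness[match(grid$station_id, st$station_id)]
  if (isTRUE(scenario$exact_missingness)) {
    missing <- logical(n)
    series <- paste(grid$station_id, grid$gear, grid$age_class)
    for (s in unique(series)) {
      idx <- which(series == s)
      k <- round(miss_p[idx[1]] * length(idx))
      if (k > 0) missing[sample(idx, k)] <- TRUE
    }
  } else {
    missing <- stats::runif(n) < miss_p
  }

  catch <- data.frame(grid[, c("station_id", "year", "month", "gear",
                               "age_class")],
                      count = count, effort = round(effort, 1))
  keep <- !missing
  truth <- list(
    outliers = catch[outlier & keep, c("station_id", "year", "month", "gear",
                                       "age_class")],
    missing = catch[missing, c("station_id", "year", "month", "gear",
                               "age_class")],
    states = x, covariate = cc)
  list(catch = catch[keep, ], stations = st, flow = flow, truth = truth)
}

#' Simulate a time-varying-regression (DLM) scenario
#'
#' Generates group-level annual responses `y[i,t] = alpha_i +
#' beta[i,t] * f_t + e[i,t]` where each group's slope path `beta[i,]`
#' follows a prescribed trajectory and `f` is a standardized annual flow
#' series.
#'
#' @param slope a trajectory spec, or a list of one per group: either
#'   `list(type = "constant", value = )`, `list(type = "ramp", from = ,
#'   to = )` (linear in time), or `list(type = "rw", start = , sd = )`
#'   (random walk).
#' @param T number of years.
#' @param alpha per-group intercepts (recycled).
#' @param sigma_obs observation noise SD (default 0.1).
#' @param flow optional standardized flow of length `T`; simulated from
#'   the scenario flow model when omitted.
#' @param scenario flow model source, a [flow_scenario()].
#' @param seed integer seed.
#' @return List: `y` (`n_groups x T`), `flow`, `beta` (true slope paths),
#'   `alpha`.
#' @export
simulate_dlm_scenario <- function(slope, T = 41L, alpha = 0, sigma_obs = 0.1,
                                  flow = NULL, scenario = flow_scenario(),
                                  seed = scenario$seed) {
  if (!is.null(slope$type)) slope <- list(slope)
  m <- length(slope)
  alpha <- rep(alpha, length.out = m)
  if (is.null(flow)) {
    sc <- scenario; sc$T <- T; sc$years <- seq_len(T) + 1979L
    fl <- simulate_flow(sc, seed = seed)
    flow <- flow_covariate_from_monthly(fl, sc$years)
  }
  stopifnot(length(flow) == T)
  set.seed(seed + 3L)
  beta <- matrix(0, m, T)
  for (i in seq_len(m)) {
    sp <- slope[[i]]
    beta[i, ] <- switch(sp$type,
      constant = rep(sp$value, T),
      ramp = seq(sp$from, sp$to, length.out = T),
      rw = sp$start + cumsum(c(0, stats::rnorm(T - 1L, 0, sp$sd))),
      stop("unknown slope trajectory type: ", sp$type))
  }
  y <- sweep(beta, 2L, flow, `*`) + alpha +
    matrix(stats::rnorm(m * T, 0, sigma_obs), m, T)
  rownames(y) <- rownames(beta) <- paste0("group", seq_len(m))
  list(y = y, flow = flow, beta = beta, alpha = alpha)
}
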