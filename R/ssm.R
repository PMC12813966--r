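#' Define a Gaussian linear state-space model
#'
#' Specifies the random-walk state-space model
#' \deqn{x_t = x_{t-1} + C c_t + w_t, \quad w_t \sim N(0, Q)}
#' \deqn{y_t = Z_t x_t + v_t, \quad v_t \sim N(0, R)}
#' with \eqn{Q} diagonal and unequal (one free variance per state), \eqn{R}
#' diagonal with optional sharing groups (one free variance per group), the
#' drift \eqn{u} and observation intercept \eqn{a} fixed to zero, and
#' \eqn{x_0 \sim N(x_0, V_0)}. This is the machinery behind both the
#' multi-station population models (time-invariant \eqn{Z}) and the
#' time-varying-coefficient dynamic linear models (\eqn{Z_t} an array that
#' carries the covariate).
#'
#' @param Z observation matrix, either `p x m` (time-invariant) or a
#'   `p x m x T` array (time-varying). Rows map observed series to states.
#' @param T number of time steps. Required when `Z` is a matrix; inferred
#'   from the third dimension otherwise.
#' @param R_groups integer (or factor) vector of length `p` assigning each
#'   observed series to an observation-variance sharing group. Default: one
#'   free variance per series ("diagonal and unequal").
#' @param Q `"diagonal-unequal"` (m free process variances, the default),
#'   `"diagonal-equal"` (one shared free variance), or a fixed non-negative
#'   numeric vector of length `m`.
#' @param covariates `q x T` matrix of state-equation covariates
#'   \eqn{c_t}, or `NULL` for no covariate.
#' @param C covariate effect: `NULL` (no covariate term), `"free"`
#'   (estimated `m x q` matrix), or a fixed numeric `m x q` matrix.
#' @param x0 `"estimated"` (free initial-state parameters, used with
#'   `V0 = 0`) or a fixed numeric vector of length `m`.
#' @param V0 initial-state variance: scalar or length-`m` vector placed on
#'   the diagonal of \eqn{V_0}. Use 0 with estimated `x0`; a diffuse value
#'   (e.g. 10) with fixed `x0 = 0` for DLM-style fits.
#' @return An object of class `ssm_spec`.
#' @export
ssm_spec <- function(Z, T = NULL, R_groups = NULL, Q = "diagonal-unequal",
                     covariates = NULL, C = NULL, x0 = "estimated", V0 = 0) {
  if (is.matrix(Z)) {
    if (is.null(T)) stop("T is required when Z is time-invariant")
    Zc <- array(Z, dim = c(nrow(Z), ncol(Z), 1L))
    dimnames(Zc) <- c(dimnames(Z), list(NULL))
  } else if (is.array(Z) && length(dim(Z)) == 3L) {
    if (is.null(T)) T <- dim(Z)[3L]
    if (dim(Z)[3L] != T) stop("third dimension of Z must equal T")
    Zc <- Z
  } else stop("Z must be a p x m matrix or a p x m x T array")
  p <- dim(Zc)[1L]; m <- dim(Zc)[2L]
  T <- as.integer(T)
  if (T < 2L) stop("need at least two time steps")

  if (is.null(R_groups)) R_groups <- seq_len(p)
  R_groups <- as.integer(factor(R_groups))
  if (length(R_groups) != p) stop("R_groups must have length p")

  Q_free <- identical(Q, "diagonal-unequal") || identical(Q, "diagonal-equal")
  Q_groups <- if (identical(Q, "diagonal-equal")) rep(1L, m) else seq_len(m)
  if (!Q_free) {
    Q <- as.numeric(Q)
    if (length(Q) == 1L) Q <- rep(Q, m)
    if (length(Q) != m || any(Q < 0)) stop("fixed Q must be m non-negative variances")
  }

  q <- 0L
  if (!is.null(covariates)) {
    covariates <- rbind(covariates)
    if (ncol(covariates) != T) stop("covariates must be q x T")
    if (!all(is.finite(covariates))) stop("covariates must be finite")
    q <- nrow(covariates)
    if (is.null(C)) C <- "free"
  }
  C_free <- identical(C, "free")
  if (C_free && q == 0L) stop("C is free but no covariates supplied")
  if (!C_free && !is.null(C)) {
    C <- matrix(as.numeric(C), m, q)
  }

  x0_free <- identical(x0, "estimated")
  if (!x0_free) {
    x0 <- as.numeric(x0)
    if (length(x0) == 1L) x0 <- rep(x0, m)
    if (length(x0) != m) stop("fixed x0 must have length m")
  }
  V0 <- as.numeric(V0)
  if (length(V0) == 1L) V0 <- rep(V0, m)
  if (length(V0) != m || any(V0 < 0)) stop("V0 must be m non-negative variances")
  if (x0_free && any(V0 > 0))
    stop("estimated x0 requires V0 = 0 (x0 is then a fixed unknown parameter)")

  structure(list(
    p = p, m = m, T = T, q = q, Z = Zc,
    R_groups = R_groups, n_R = max(R_groups),
    Q_free = Q_free, Q_fixed = if (Q_free) NULL else Q,
    Q_groups = Q_groups, n_Q = max(Q_groups),
    C_free = C_free, C_fixed = if (C_free || q == 0L) NULL else C,
    covariates = covariates,
    x0_free = x0_free, x0_fixed = if (x0_free) NULL else x0,
    V0 = V0,
    state_names = dimnames(Zc)[[2L]], series_names = dimnames(Zc)[[1L]]
  ), class = "ssm_spec")
}

#' @export
print.ssm_spec <- function(x, ...) {
  cat(sprintf("ssm_spec: %d series, %d states, T = %d%s\n", x$p, x$m, x$T,
              if (dim(x$Z)[3L] > 1L) " (time-varying Z)" else ""))
  cat(sprintf("  Q: %s; R: %d group(s); C: %s; x0: %s\n",
              if (x$Q_free) "diagonal-unequal (free)" else "fixed",
              x$n_R,
              if (x$C_free) sprintf("free (%d x %d)", x$m, x$q)
              else if (x$q > 0L) "fixed" else "none",
              if (x$x0_free) "estimated" else "fixed"))
  invisible(x)
}

# --- parameter plumbing ------------------------------------------------------

# params is a plain list: Q (length m), R (length n_R), C (m x q or NULL),
# x0 (length m). Fixed blocks are carried too so the filter never branches.
ssm_params <- function(spec, Q = NULL, R = NULL, C = NULL, x0 = NULL) {
  list(
    Q = if (spec$Q_free) Q else spec$Q_fixed,
    R = R,
    C = if (spec$C_free) C else spec$C_fixed,
    x0 = if (spec$x0_free) x0 else spec$x0_fixed
  )
}

check_params <- function(spec, params) {
  stopifnot(length(params$Q) == spec$m, length(params$R) == spec$n_R,
            length(params$x0) == spec$m)
  if (any(!is.finite(params$Q)) || any(params$Q < 0)) stop("Q variances must be finite and >= 0")
  if (any(!is.finite(params$R)) || any(params$R < 0)) stop("R variances must be finite and >= 0")
  if (!all(is.finite(params$x0))) stop("x0 must be finite")
  if (spec$q > 0L && (is.null(params$C) || !all(is.finite(params$C))))
    stop("C must be a finite m x q matrix")
  invisible(TRUE)
}

# covariate contribution C c_t as an m x T matrix (zeros when no covariate)
cc_term <- function(spec, params) {
  if (spec$q == 0L) return(matrix(0, spec$m, spec$T))
  matrix(params$C, spec$m, spec$q) %*% spec$covariates
}

expand_R <- function(spec, params) params$R[spec$R_groups]

check_y <- function(spec, y) {
  if (!is.matrix(y) || nrow(y) != spec$p || ncol(y) != spec$T)
    stop(sprintf("y must be a %d x %d matrix", spec$p, spec$T))
  if (any(is.infinite(y))) stop("y contains non-finite (infinite) values")
  if (all(is.na(y))) stop("y is entirely missing")
  invisible(TRUE)
}

run_kalman <- function(spec, params, y, smooth) {
  .kalman_cpp(y, spec$Z, params$Q, expand_R(spec, params),
              cc_term(spec, params), params$x0, spec$V0, smooth)
}

#' Kalman filter with missing data
#'
#' Runs the forward filter for an [ssm_spec()] model, marginalising missing
#' observation components out of each update (a fully missing time step is a
#' pure prediction step), and returns the exact Gaussian log-likelihood.
#'
#' @param spec an [ssm_spec()].
#' @param params parameter list with elements `Q` (length m), `R` (one
#'   variance per sharing group), `C` (`m x q`, when the spec has
#'   covariates) and `x0` (length m). Fixed blocks may be omitted.
#' @param y `p x T` observation matrix; `NA` marks missing values.
#' @return List with `loglik`, predicted (`xp`, `Pp`) and filtered
#'   (`xf`, `Pf`) state moments.
#' @export
kalman_filter <- function(spec, params, y) {
  params <- ssm_params(spec, params$Q, params$R, params$C, params$x0)
  check_params(spec, params); check_y(spec, y)
  out <- run_kalman(spec, params, y, smooth = FALSE)
  out[c("loglik", "xp", "Pp", "xf", "Pf")]
}

#' Kalman (RTS) smoother with missing data
#'
#' Returns the smoothed state moments — the conditional means and
#' covariances of the states given all observations — together with the
#' lag-one smoothed covariances and the log-likelihood.
#'
#' @inheritParams kalman_filter
#' @return List with `loglik`, smoothed means `xs` (`m x T`), covariances
#'   `Ps` (`m x m x T`), lag-one covariances `Pcs` (slice `t` holds
#'   `cov(x_t, x_{t-1} | y)`), and the smoothed initial-state moments
#'   `xs0`, `Ps0`.
#' @export
kalman_smoother <- function(spec, params, y) {
  params <- ssm_params(spec, params$Q, params$R, params$C, params$x0)
  check_params(spec, params); check_y(spec, y)
  out <- run_kalman(spec, params, y, smooth = TRUE)
  out[c("loglik", "xs", "Ps", "Pcs", "xs0", "Ps0", "xf", "Pf", "xp", "Pp")]
}

# --- maximum likelihood ------------------------------------------------------

VAR_FLOOR <- 1e-10

default_control <- function(control) {
  utils::modifyList(list(
    em_tol = 1e-6, em_maxit = 5000L,
    bfgs_maxit = 500L, bfgs_warmup = 20L, bfgs_reltol = 1e-12
  ), control)
}

init_params <- function(spec, y) {
  # moment-based start: split the pooled variance of mapped series between
  # process and observation, start states at early-series means
  Zbar <- if (dim(spec$Z)[3L] > 1L) apply(spec$Z, c(1, 2), mean)
          else matrix(spec$Z[, , 1L], spec$p, spec$m)
  v <- stats::var(as.numeric(y), na.rm = TRUE)
  if (!is.finite(v) || v <= 0) v <- 1
  x0 <- numeric(spec$m)
  first <- y[, seq_len(min(3L, spec$T)), drop = FALSE]
  for (j in seq_len(spec$m)) {
    w <- abs(Zbar[, j]) > 0
    mj <- mean(first[w, , drop = FALSE], na.rm = TRUE)
    x0[j] <- if (is.finite(mj)) mj else mean(y, na.rm = TRUE)
  }
  if (!spec$x0_free) x0 <- spec$x0_fixed
  ssm_params(spec,
             Q = rep(v / 2, spec$m),
             R = rep(v / 2, spec$n_R),
             C = if (spec$C_free) matrix(0, spec$m, spec$q) else NULL,
             x0 = x0)
}

# one EM sweep: E-step at `params`, conditional M-steps for each free block
# (ECM; every update maximises the expected complete-data log-likelihood
# given the other blocks, so the likelihood never decreases)
em_step <- function(spec, params, y, obs_mask, n_obs_by_group) {
  ks <- run_kalman(spec, params, y, smooth = TRUE)
  m <- spec$m; T <- spec$T
  xs <- ks$xs; Ps <- ks$Ps; Pcs <- ks$Pcs
  XS0 <- cbind(ks$xs0, xs)                     # m x (T+1), column t+1 = xs_t

  newp <- params

  # C given current x0 (differences use the smoothed x0)
  if (spec$C_free) {
    D <- XS0[, 2:(T + 1), drop = FALSE] - XS0[, 1:T, drop = FALSE]  # E[x_t - x_{t-1}]
    Scc <- spec$covariates %*% t(spec$covariates)
    newp$C <- t(solve(Scc, spec$covariates %*% t(D)))
  }
  cc <- cc_term(spec, newp)

  # x0 given new C (V0 = 0 case: x0 is a parameter, maximised exactly)
  if (spec$x0_free) newp$x0 <- xs[, 1L] - cc[, 1L]

  # Q: diagonal of (1/T) sum_t E[(x_t - x_{t-1} - Cc_t)(...)']
  if (spec$Q_free) {
    xs_prev <- XS0[, 1:T, drop = FALSE]
    Ps0_prev <- ks$Ps0
    if (spec$x0_free) { xs_prev[, 1L] <- newp$x0; Ps0_prev <- matrix(0, m, m) }
    d <- xs - xs_prev - cc
    sq <- numeric(m)
    dg <- function(A) matrix(A, m, m)[cbind(seq_len(m), seq_len(m))]
    for (t in seq_len(T)) {
      Pprev <- if (t == 1L) Ps0_prev else Ps[, , t - 1L]
      Pc <- if (t == 1L && spec$x0_free) matrix(0, m, m) else Pcs[, , t]
      sq <- sq + dg(Ps[, , t]) + dg(Pprev) - 2 * dg(Pc) + d[, t]^2
    }
    qg <- vapply(seq_len(spec$n_Q), function(g)
      mean(sq[spec$Q_groups == g]) / T, numeric(1))
    newp$Q <- pmax(qg[spec$Q_groups], VAR_FLOOR)
  }

  # R by sharing group over observed cells
  tvZ <- dim(spec$Z)[3L] > 1L
  fit_mean <- matrix(0, spec$p, T)
  pvar <- matrix(0, spec$p, T)
  for (t in seq_len(T)) {
    Zt <- matrix(spec$Z[, , if (tvZ) t else 1L], spec$p, m)
    fit_mean[, t] <- Zt %*% xs[, t]
    pvar[, t] <- rowSums((Zt %*% Ps[, , t]) * Zt)
  }
  res2 <- (y - fit_mean)^2 + pvar
  sums <- vapply(seq_len(spec$n_R), function(g) {
    sum(res2[spec$R_groups == g, , drop = FALSE][obs_mask[spec$R_groups == g, , drop = FALSE]])
  }, numeric(1))
  newp$R <- pmax(sums / n_obs_by_group, VAR_FLOOR)

  list(params = newp, loglik = ks$loglik)
}

n_free_params <- function(spec) {
  (if (spec$Q_free) spec$n_Q else 0L) + spec$n_R +
    (if (spec$x0_free) spec$m else 0L) +
    (if (spec$C_free) spec$m * spec$q else 0L)
}

# pack free parameters into an unconstrained vector (variances on log scale)
pack_params <- function(spec, params) {
  th <- c(if (spec$Q_free) log(pmax(params$Q[!duplicated(spec$Q_groups)], VAR_FLOOR)),
          log(pmax(params$R, VAR_FLOOR)),
          if (spec$x0_free) params$x0,
          if (spec$C_free) as.numeric(params$C))
  names(th) <- param_names(spec)
  th
}

unpack_params <- function(spec, theta) {
  i <- 0L
  take <- function(n) { out <- unname(theta[i + seq_len(n)]); i <<- i + n; out }
  Q <- if (spec$Q_free) exp(take(spec$n_Q))[spec$Q_groups] else NULL
  R <- exp(take(spec$n_R))
  x0 <- if (spec$x0_free) take(spec$m) else NULL
  C <- if (spec$C_free) matrix(take(spec$m * spec$q), spec$m, spec$q) else NULL
  ssm_params(spec, Q = Q, R = R, C = C, x0 = x0)
}

param_names <- function(spec) {
  sn <- spec$state_names
  if (is.null(sn)) sn <- paste0("state", seq_len(spec$m))
  c(if (spec$Q_free) paste0("Q.", if (spec$n_Q == spec$m) sn else
      paste0("group", seq_len(spec$n_Q))),
    paste0("R.group", seq_len(spec$n_R)),
    if (spec$x0_free) paste0("x0.", sn),
    if (spec$C_free) paste0("C.", as.character(outer(sn, seq_len(spec$q),
                                                     function(a, b) paste0(a, ".c", b)))))
}

param_block <- function(spec) {
  c(if (spec$Q_free) rep("Q", spec$n_Q), rep("R", spec$n_R),
    if (spec$x0_free) rep("x0", spec$m), if (spec$C_free) rep("C", spec$m * spec$q))
}

#' Maximum-likelihood fit of a state-space model
#'
#' Fits all free parameters of an [ssm_spec()] by maximum likelihood, either
#' by EM (closed-form conditional M-steps for the diagonal variance
#' structures, guaranteed non-decreasing likelihood) or by BFGS on the
#' unconstrained parameterisation (variances on the log scale) after a short
#' EM warm start.
#'
#' @inheritParams kalman_filter
#' @param method `"bfgs"` (default; EM warm start then quasi-Newton) or
#'   `"em"`.
#' @param control list; recognised entries `em_tol` (default `1e-6`),
#'   `em_maxit` (5000), `bfgs_maxit` (500), `bfgs_warmup` (20 EM
#'   iterations), `bfgs_reltol`.
#' @param params optional starting values (as for [kalman_filter()]).
#' @return An object of class `ssm_fit`: parameter estimates, `loglik`,
#'   free-parameter count `k`, number of non-missing scalar observations
#'   `n`, `AICc`, smoothed states (`$states$mean`, `$states$se`),
#'   convergence diagnostics, and the EM likelihood trace when applicable.
#' @export
fit_ml <- function(spec, y, method = c("bfgs", "em"), control = list(),
                   params = NULL) {
  method <- match.arg(method)
  ctl <- default_control(control)
  check_y(spec, y)
  k <- n_free_params(spec)
  if (k == 0L) stop("model has no free parameters")
  if (is.null(params)) params <- init_params(spec, y)
  params <- ssm_params(spec, params$Q, params$R, params$C, params$x0)
  check_params(spec, params)

  obs_mask <- !is.na(y)
  n_obs_by_group <- vapply(seq_len(spec$n_R), function(g)
    sum(obs_mask[spec$R_groups == g, , drop = FALSE]), numeric(1))
  if (any(n_obs_by_group == 0))
    stop("an observation-variance group has no observed values")

  run_em <- function(params, maxit, tol) {
    trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    it <- 0L
    while (it < maxit) {
      it <- it + 1L
      st <- em_step(spec, params, y, obs_mask, n_obs_by_group)
      params <- st$params
      trace <- c(trace, st$loglik)
      if (is.finite(ll_prev) && abs(st$loglik - ll_prev) < tol) {
        converged <- TRUE
        break
      }
      ll_prev <- st$loglik
    }
    list(params = params, trace = trace, iterations = it, converged = converged)
  }

  if (method == "em") {
    em <- run_em(params, ctl$em_maxit, ctl$em_tol)
    params <- em$params
    final_ll <- run_kalman(spec, params, y, smooth = FALSE)$loglik
    conv <- list(method = "em", iterations = em$iterations,
                 converged = em$converged,
                 loglik_delta = if (length(em$trace) > 1L)
                   abs(diff(utils::tail(em$trace, 2L))) else NA_real_)
    trace <- em$trace
  } else {
    warm <- run_em(params, ctl$bfgs_warmup, ctl$em_tol)
    th0 <- pack_params(spec, warm$params)
    negll <- function(theta) {
      p <- unpack_params(spec, theta)
      -tryCatch(run_kalman(spec, p, y, smooth = FALSE)$loglik,
                error = function(e) -Inf)
    }
    opt <- stats::optim(th0, negll, method = "BFGS",
                        control = list(maxit = ctl$bfgs_maxit,
                                       reltol = ctl$bfgs_reltol))
    params <- unpack_params(spec, opt$par)
    final_ll <- -opt$value
    conv <- list(method = "bfgs", iterations = opt$counts[["function"]],
                 converged = opt$convergence == 0L,
                 loglik_delta = NA_real_)
    trace <- warm$trace
  }

  n <- sum(obs_mask)
  sm <- run_kalman(spec, params, y, smooth = TRUE)
  se <- sqrt(pmax(apply(sm$Ps, 3L, diag), 0))
  se <- matrix(se, spec$m, spec$T)
  sn <- spec$state_names
  if (!is.null(sn)) rownames(sm$xs) <- rownames(se) <- sn

  structure(list(
    spec = spec, params = params, loglik = final_ll, k = k, n = n,
    AICc = if (n - k - 1 > 0) aicc(final_ll, k, n) else NA_real_,
    states = list(mean = sm$xs, var = sm$Ps, se = se),
    convergence = conv, loglik_trace = trace, y = y
  ), class = "ssm_fit")
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat(sprintf("ssm_fit (%s): loglik = %.4f, k = %d, n = %d, AICc = %.4f\n",
              x$convergence$method, x$loglik, x$k, x$n, x$AICc))
  cat(sprintf("  converged: %s (%d iterations)\n",
              x$convergence$converged, x$convergence$iterations))
  invisible(x)
}

#' @export
logLik.ssm_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' Serialize a fitted state-space model
#'
#' Writes the fit as JSON (model shape fingerprint, parameter estimates,
#' log-likelihood, `k`, `n`, AICc, convergence diagnostics) and,
#' optionally, the smoothed states as a CSV of one row per state.
#'
#' @param fit an [fit_ml()] result.
#' @param path JSON output path.
#' @param states_path optional CSV path for the smoothed state means and
#'   standard errors.
#' @return `path`, invisibly.
#' @export
write_ssm_fit <- function(fit, path, states_path = NULL) {
  stopifnot(inherits(fit, "ssm_fit"))
  spec <- fit$spec
  obj <- list(
    model = list(p = spec$p, m = spec$m, T = spec$T, q = spec$q,
                 n_R_groups = spec$n_R, n_Q_groups = spec$n_Q,
                 time_varying_Z = dim(spec$Z)[3L] > 1L,
                 Q_free = spec$Q_free, C_free = spec$C_free,
                 x0_free = spec$x0_free),
    estimates = list(Q = fit$params$Q, R = fit$params$R,
                     C = fit$params$C, x0 = fit$params$x0),
    loglik = fit$loglik, k = fit$k, n = fit$n, AICc = fit$AICc,
    convergence = fit$convergence)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(states_path)) {
    sn <- rownames(fit$states$mean)
    if (is.null(sn)) sn <- paste0("state", seq_len(spec$m))
    utils::write.csv(
      data.frame(state = rep(sn, 2L),
                 quantity = rep(c("mean", "se"), each = spec$m),
                 rbind(fit$states$mean, fit$states$se), check.names = FALSE),
      states_path, row.names = FALSE)
  }
  invisible(path)
}

#' Small-sample corrected AIC
#'
#' \eqn{AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)}, with `n` the number of
#' non-missing scalar observations and `k` the free-parameter count.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of free parameters.
#' @param n number of non-missing scalar observations.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: need n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Wald confidence intervals for state-space parameters
#'
#' Intervals from the numerically differentiated Hessian of the
#' log-likelihood in the unconstrained parameterisation (variances on the
#' log scale, back-transformed by exponentiating the interval endpoints).
#' Parameters whose curvature is not negative definite get `NA` limits
#' rather than an error.
#'
#' @param fit an [fit_ml()] result.
#' @param level confidence level (default 0.95).
#' @return Data frame with one row per free parameter: `parameter`,
#'   `block` (`Q`, `R`, `x0` or `C`), `estimate`, `lower`, `upper`.
#' @export
param_confint <- function(fit, level = 0.95) {
  spec <- fit$spec; y <- fit$y
  th <- pack_params(spec, fit$params)
  ll <- function(theta) {
    p <- unpack_params(spec, theta)
    tryCatch(run_kalman(spec, p, y, smooth = FALSE)$loglik,
             error = function(e) NA_real_)
  }
  H <- numDeriv::hessian(ll, th)
  V <- tryCatch(solve(-H), error = function(e) NULL)
  se <- rep(NA_real_, length(th))
  if (!is.null(V)) {
    dv <- diag(V)
    se[dv > 0 & is.finite(dv)] <- sqrt(dv[dv > 0 & is.finite(dv)])
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  blocks <- param_block(spec)
  lower <- th - z * se
  upper <- th + z * se
  est <- th
  on_log <- blocks %in% c("Q", "R")
  est[on_log] <- exp(th[on_log])
  lower[on_log] <- exp(lower[on_log])
  upper[on_log] <- exp(upper[on_log])
  data.frame(parameter = param_names(spec), block = blocks,
             estimate = unname(est), lower = unname(lower),
             upper = unname(upper), row.names = NULL)
}
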