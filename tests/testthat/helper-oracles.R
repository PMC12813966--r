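# Brute-force joint-Gaussian oracles for the state-space engine.
#
# For the random-walk model x_t = x_{t-1} + cc_t + w_t, x_0 ~ N(x0, V0),
# the stacked state vector (x_1, ..., x_T) is Gaussian with
#   E[x_t]        = x0 + sum_{s<=t} cc_s
#   cov(x_s, x_t) = V0 + min(s, t) * Q      (diagonal blocks, elementwise)
# so the observed vector is Gaussian too, and both the likelihood and the
# smoothed moments follow from dense linear algebra. Everything here is
# plain R on small instances, independent of the package's filter code.

# joint moments of the stacked states (m*T) and observations (p*T)
joint_moments <- function(Z, Q, R, x0, V0, cc = NULL) {
  m <- length(Q); T <- if (is.matrix(Z)) NA else dim(Z)[3]
  if (is.matrix(Z)) stop("pass Z as a p x m x T array")
  T <- dim(Z)[3]; p <- dim(Z)[1]
  if (is.null(cc)) cc <- matrix(0, m, T)
  mu_x <- apply(cc, 1, cumsum)            # T x m
  mu_x <- t(mu_x + rep(x0, each = T))     # m x T
  SX <- matrix(0, m * T, m * T)
  for (s in 1:T) for (t in 1:T) {
    SX[((s - 1) * m + 1):(s * m), ((t - 1) * m + 1):(t * m)] <-
      diag(V0 + pmin(s, t) * Q, m)
  }
  ZZ <- matrix(0, p * T, m * T)
  for (t in 1:T)
    ZZ[((t - 1) * p + 1):(t * p), ((t - 1) * m + 1):(t * m)] <- Z[, , t]
  list(mu_x = as.numeric(mu_x), SX = SX, ZZ = ZZ,
       mu_y = as.numeric(ZZ %*% as.numeric(mu_x)),
       SY = ZZ %*% SX %*% t(ZZ) + diag(rep(R, T), p * T))
}

# exact marginal log-density of the observed cells of y (p x T, NA missing)
oracle_loglik <- function(y, Z, Q, R, x0, V0, cc = NULL) {
  jm <- joint_moments(Z, Q, R, x0, V0, cc)
  obs <- which(!is.na(as.numeric(y)))
  yo <- as.numeric(y)[obs]
  mu <- jm$mu_y[obs]
  S <- jm$SY[obs, obs, drop = FALSE]
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * (length(yo) * log(2 * pi) + ld +
            drop(t(yo - mu) %*% solve(S, yo - mu)))
}

# conditional (smoothed) state moments given the observed cells
oracle_smooth <- function(y, Z, Q, R, x0, V0, cc = NULL) {
  jm <- joint_moments(Z, Q, R, x0, V0, cc)
  m <- length(Q); T <- dim(Z)[3]
  obs <- which(!is.na(as.numeric(y)))
  yo <- as.numeric(y)[obs]
  Sxy <- jm$SX %*% t(jm$ZZ)
  Syy <- jm$SY[obs, obs, drop = FALSE]
  mu <- jm$mu_x + Sxy[, obs, drop = FALSE] %*%
    solve(Syy, yo - jm$mu_y[obs])
  S <- jm$SX - Sxy[, obs, drop = FALSE] %*%
    solve(Syy, t(Sxy[, obs, drop = FALSE]))
  list(xs = matrix(mu, m, T),
       Ps = array(vapply(1:T, function(t) {
         idx <- ((t - 1) * m + 1):(t * m)
         as.numeric(S[idx, idx, drop = FALSE])
       }, numeric(m * m)), dim = c(m, m, T)))
}

# a random small instance (m * T <= 12) with random PSD diagonal
# parameters, random Z and random missingness; never all-missing
random_small_model <- function(seed, time_varying_Z = FALSE) {
  set.seed(seed)
  repeat {
    m <- sample(1:3, 1)
    T <- sample(2:min(6, 12 %/% m), 1)
    p <- sample(1:4, 1)
    Z <- array(stats::rnorm(p * m * T), dim = c(p, m, T))
    if (!time_varying_Z) Z <- array(Z[, , 1], dim = c(p, m, T))
    Q <- stats::runif(m, 0.05, 2)
    R <- stats::runif(p, 0.05, 2)
    V0 <- stats::runif(m, 0, 1)
    x0 <- stats::rnorm(m)
    q <- sample(0:1, 1)
    cc <- if (q) matrix(stats::rnorm(m) %*% t(stats::rnorm(T)), m, T)
          else NULL
    jm <- joint_moments(Z, Q, R, x0, V0, cc)
    yv <- jm$mu_y + drop(t(chol(jm$SY + diag(1e-12, nrow(jm$SY)))) %*%
                           stats::rnorm(p * T))
    y <- matrix(yv, p, T)
    y[stats::runif(p * T) < 0.25] <- NA
    if (any(!is.na(y))) break
  }
  list(y = y, Z = Z, Q = Q, R = R, x0 = x0, V0 = V0, cc = cc,
       m = m, p = p, T = T)
}

# run the package filter/smoother on a random_small_model instance
pkg_kalman <- function(inst, smooth = FALSE) {
  # an arbitrary cc sequence enters the spec as C = cc with the T x T
  # identity as the covariate matrix, so C c_t = cc_t exactly
  spec <- if (is.null(inst$cc))
    ssm_spec(inst$Z, T = inst$T, Q = inst$Q, x0 = inst$x0, V0 = inst$V0)
  else
    ssm_spec(inst$Z, T = inst$T, Q = inst$Q, x0 = inst$x0, V0 = inst$V0,
             covariates = diag(inst$T), C = inst$cc)
  params <- list(Q = inst$Q, R = inst$R, x0 = inst$x0,
                 C = if (!is.null(inst$cc)) inst$cc)
  if (smooth) kalman_smoother(spec, params, inst$y)
  else kalman_filter(spec, params, inst$y)
}

# brute-force Theil-Sen: explicit double loop over all pairs
brute_theil_sen <- function(y, t = seq_along(y)) {
  force(t)
  ok <- !is.na(y); y <- y[ok]; t <- t[ok]
  s <- c()
  for (i in seq_along(y)) for (j in seq_along(y)) {
    if (i < j) s <- c(s, (y[j] - y[i]) / (t[j] - t[i]))
  }
  stats::median(s)
}
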