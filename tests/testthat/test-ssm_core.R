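test_that("filter log-likelihood equals the joint-Gaussian density on random small models", {
  for (seed in 1:40) {
    inst <- random_small_model(seed, time_varying_Z = seed %% 2 == 0)
    kf <- pkg_kalman(inst)
    ll_o <- oracle_loglik(inst$y, inst$Z, inst$Q, inst$R, inst$x0, inst$V0,
                          inst$cc)
    expect_lt(abs(kf$loglik - ll_o), 1e-8)
  }
})

test_that("an iid degenerate model reduces to the standard normal density", {
  # 1 state, Z = [1], x0 = 0 with V0 = 0, Q = 0, R = 1: y are iid N(0, 1)
  spec <- ssm_spec(matrix(1, 1, 1), T = 2, Q = 0, x0 = 0, V0 = 0)
  kf <- kalman_filter(spec, list(R = 1), matrix(c(0, 0), 1, 2))
  expect_equal(kf$loglik, -log(2 * pi), tolerance = 1e-12)
})

test_that("smoothed moments equal joint-Gaussian conditioning on random small models", {
  for (seed in 1:40) {
    inst <- random_small_model(seed + 100, time_varying_Z = seed %% 2 == 0)
    ks <- pkg_kalman(inst, smooth = TRUE)
    or <- oracle_smooth(inst$y, inst$Z, inst$Q, inst$R, inst$x0, inst$V0,
                        inst$cc)
    expect_lt(max(abs(ks$xs - or$xs)), 1e-8)
    expect_lt(max(abs(ks$Ps - or$Ps)), 1e-8)
    expect_true(all(apply(ks$Ps, 3, diag) >= -1e-12))
  }
})

test_that("degenerate state (Q = 0, V0 = 0) smooths to a constant equal to the terminal filtered state", {
  spec <- ssm_spec(matrix(c(1, 1), 2, 1), T = 5, Q = 0, x0 = 0.7, V0 = 0)
  y <- matrix(rnorm(10), 2, 5)
  ks <- kalman_smoother(spec, list(R = c(1, 1)), y)
  kf <- kalman_filter(spec, list(R = c(1, 1)), y)
  expect_equal(max(abs(ks$xs - ks$xs[1, 1])), 0, tolerance = 1e-12)
  expect_equal(ks$xs[1, 5], kf$xf[1, 5], tolerance = 1e-12)
})

test_that("in the R -> 0 limit with identity Z the smoothed states equal the observations", {
  set.seed(3)
  spec <- ssm_spec(diag(2), T = 6)
  y <- matrix(rnorm(12), 2, 6)
  y[1, 3] <- NA
  ks <- kalman_smoother(spec, list(Q = c(1, 1), R = c(1e-12, 1e-12),
                                   x0 = y[, 1]), y)
  expect_lt(max(abs(ks$xs[!is.na(y)] - y[!is.na(y)])), 1e-4)
})

test_that("the likelihood is invariant under permuting observation rows with Z and R", {
  inst <- random_small_model(7)
  perm <- sample(inst$p)
  inst2 <- inst
  inst2$y <- inst$y[perm, , drop = FALSE]
  inst2$Z <- inst$Z[perm, , , drop = FALSE]
  inst2$R <- inst$R[perm]
  expect_equal(pkg_kalman(inst)$loglik, pkg_kalman(inst2)$loglik,
               tolerance = 1e-10)
})

test_that("invalid inputs are rejected with informative errors", {
  spec <- ssm_spec(matrix(1, 1, 1), T = 3)
  p <- list(Q = 1, R = 1, x0 = 0)
  y <- matrix(c(1, Inf, 0), 1, 3)
  expect_error(kalman_filter(spec, p, y), "finite")
  expect_error(kalman_filter(spec, p, matrix(NA_real_, 1, 3)), "missing")
  expect_error(kalman_filter(spec, list(Q = -1, R = 1, x0 = 0),
                             matrix(0, 1, 3)), "Q")
  # zero innovation variance: Q = 0, V0 = 0, R = 0 makes F singular at t = 1
  spec0 <- ssm_spec(matrix(1, 1, 1), T = 3, Q = 0, x0 = 0, V0 = 0)
  expect_error(kalman_filter(spec0, list(R = 0), matrix(0, 1, 3)),
               "singular at time step 1")
})

test_that("EM never decreases the log-likelihood", {
  for (seed in 1:10) {
    inst <- random_small_model(seed + 300)
    spec <- ssm_spec(inst$Z, T = inst$T)
    fit <- fit_ml(spec, inst$y, method = "em",
                  control = list(em_maxit = 150))
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  }
})

test_that("the degenerate random-walk-free model recovers the closed-form MLE", {
  set.seed(11)
  y <- matrix(rnorm(30, 2, 1.5), 1, 30)
  spec <- ssm_spec(matrix(1, 1, 1), T = 30, Q = 0, V0 = 0)
  fit <- fit_ml(spec, y, method = "bfgs")
  expect_equal(fit$params$x0, mean(y), tolerance = 1e-6)
  expect_equal(fit$params$R, mean((y - mean(y))^2), tolerance = 1e-6)
})

test_that("EM and BFGS agree in log-likelihood on a small instance", {
  set.seed(21)
  spec <- ssm_spec(matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2), T = 30)
  x <- apply(matrix(rnorm(60, 0, 0.5), 2, 30), 1, cumsum)
  y <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2) %*% t(x) +
    matrix(rnorm(120, 0, 0.6), 4, 30)
  f_em <- fit_ml(spec, y, method = "em")
  f_bf <- fit_ml(spec, y, method = "bfgs")
  expect_lt(abs(f_em$loglik - f_bf$loglik), 1e-4)
})

test_that("parameter recovery: Q and R diagonals within 30% median relative error", {
  errs <- sapply(1:12, function(seed) {
    set.seed(seed + 500)
    m <- 2; p <- 4; T <- 200
    Z <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), p, m)
    Qt <- c(0.3, 0.6); Rt <- rep(0.4, p)
    x <- rbind(cumsum(rnorm(T, 0, sqrt(Qt[1]))), cumsum(rnorm(T, 0, sqrt(Qt[2]))))
    y <- Z %*% x + matrix(rnorm(p * T, 0, sqrt(Rt[1])), p, T)
    fit <- fit_ml(ssm_spec(Z, T = T), y, method = "em",
                  control = list(em_tol = 1e-5))
    max(abs(c(fit$params$Q / Qt - 1, fit$params$R / Rt - 1)))
  })
  expect_lt(median(errs), 0.3)
})

test_that("AICc follows its closed form and rejects undersized samples", {
  expect_equal(aicc(0, 0, 10), 0)
  expect_equal(aicc(-10, 3, 20), 27.5)
  expect_error(aicc(-10, 9, 10), "n > k")
})

test_that("fits round-trip through the JSON serializer", {
  set.seed(15)
  y <- matrix(rnorm(40), 2, 20)
  fit <- fit_ml(ssm_spec(diag(2), T = 20), y, method = "em",
                control = list(em_maxit = 50))
  jf <- tempfile(fileext = ".json"); cf <- tempfile(fileext = ".csv")
  write_ssm_fit(fit, jf, states_path = cf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(back$loglik, fit$loglik)
  expect_equal(back$estimates$Q, fit$params$Q)
  expect_equal(back$model$m, 2)
  st <- read.csv(cf, check.names = FALSE)
  expect_equal(nrow(st), 4)  # 2 states x (mean, se)
})

test_that("Wald intervals approach the classical normal-mean interval", {
  set.seed(5)
  T <- 400
  y <- matrix(rnorm(T, 1, 2), 1, T)
  spec <- ssm_spec(matrix(1, 1, 1), T = T, Q = 0, V0 = 0)
  fit <- fit_ml(spec, y, method = "bfgs")
  ci <- param_confint(fit)
  x0_row <- ci[ci$block == "x0", ]
  half <- 1.96 * sqrt(fit$params$R) / sqrt(T)
  expect_equal(x0_row$upper - x0_row$estimate, half, tolerance = 0.05 * half + 1e-8)
  # fixed parameters get no CI row
  expect_false(any(ci$block == "Q"))
})
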