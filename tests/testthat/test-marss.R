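demo_labels <- function(n_stations = 25) {
  series_labels <- flowssm:::series_labels
  series_labels(flow_scenario(n_stations = n_stations), "age0")
}

test_that("hypothesis Z matrices are one-hot with the expected state counts", {
  lab <- demo_labels(25)
  Z6 <- build_hypothesis_Z(lab, "H6")
  expect_equal(dim(Z6), c(50, 4))
  expect_true(all(rowSums(Z6) == 1))
  expect_true(all(Z6 %in% c(0, 1)))
  expect_setequal(colnames(Z6), c("channel.midwater", "channel.otter",
                                  "shoal.midwater", "shoal.otter"))

  Z1 <- build_hypothesis_Z(lab, "H1")
  expect_equal(dim(Z1), c(50, 1))
  expect_true(all(Z1 == 1))

  Z4 <- build_hypothesis_Z(lab, "H4")
  expect_equal(ncol(Z4), 6)

  expect_equal(hypothesis_table()$n_states, c(1, 2, 3, 6, 2, 4))

  lab_bad <- lab; lab_bad$gear <- NULL
  expect_error(build_hypothesis_Z(lab_bad, "H6"), "gear")
})

test_that("hypothesis comparison ranks by AICc, breaks ties by k, keeps non-converged flagged", {
  sc <- flow_scenario(seed = 12, n_stations = 6, C = NULL, Q = 0.3, R = 0.3)
  sim <- simulate_ssm(sc)
  tab <- compare_hypotheses(sim$y, sim$labels, hypotheses = c("H2", "H2", "H1"))
  expect_equal(tab$AICc[1], tab$AICc[2], tolerance = 1e-8)
  expect_equal(min(tab$dAICc), 0)
  expect_equal(tab$AICc, sort(tab$AICc))
  expect_error(compare_hypotheses(sim$y, sim$labels, hypotheses = "H1"),
               "two hypotheses")
})

test_that("data generated under a gear split prefers the gear hypothesis over panmixia", {
  sc <- flow_scenario(seed = 31, n_stations = 8, hypothesis = "H2",
                      Q = 0.4, R = 0.2, C = NULL)
  sim <- simulate_ssm(sc)
  tab <- compare_hypotheses(sim$y, sim$labels, hypotheses = c("H1", "H2"))
  expect_equal(tab$hypothesis[1], "H2")
})

test_that("the likelihood is equivariant under relabeling series and states", {
  sc <- flow_scenario(seed = 17, n_stations = 6, C = NULL)
  sim <- simulate_ssm(sc)
  Rg <- flowssm:::make_R_groups(sim$labels, "region_gear")
  spec <- ssm_spec(build_hypothesis_Z(sim$labels, "H6"), T = ncol(sim$y),
                   R_groups = Rg)
  fit <- fit_ml(spec, sim$y, method = "em", control = list(em_maxit = 200))

  perm <- sample(nrow(sim$y))
  lab2 <- sim$labels[perm, ]
  spec2 <- ssm_spec(build_hypothesis_Z(lab2, "H6"), T = ncol(sim$y),
                    R_groups = Rg[perm])
  fit2 <- fit_ml(spec2, sim$y[perm, , drop = FALSE], method = "em",
                 control = list(em_maxit = 200))
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-6)
  # states carry the same group names, so Q estimates match up to labels
  expect_equal(fit$params$Q[order(colnames(spec$Z[, , 1]))],
               fit2$params$Q[order(colnames(spec2$Z[, , 1]))],
               tolerance = 1e-4)
})

test_that("the flow-covariate model recovers effect signs and rejects degenerate covariates", {
  sc <- flow_scenario(seed = 23, n_stations = 10)
  sim <- simulate_ssm(sc)
  fe <- fit_flow_effect(sim$y, sim$labels, sim$covariate)
  est <- fe$effects$estimate[match(c("channel.midwater", "shoal.midwater"),
                                   fe$effects$state)]
  # truth is C = (0.5, 0, 0.25, 0) on (channel.mw, channel.ot, shoal.mw, shoal.ot)
  expect_equal(est, c(0.5, 0.25), tolerance = 0.35)
  expect_true(all(fe$effects$lower <= fe$effects$estimate &
                    fe$effects$estimate <= fe$effects$upper, na.rm = TRUE))
  expect_error(fit_flow_effect(sim$y, sim$labels, rep(0, ncol(sim$y))),
               "constant")
})

test_that("extracted states equal the observations when observation error vanishes", {
  set.seed(2)
  y <- matrix(cumsum(rnorm(30, 0, 0.5)), 1, 30) # one random-walk series
  spec <- ssm_spec(matrix(1, 1, 1), T = 30, Q = 1e-0, x0 = y[1, 1], V0 = 0)
  params <- list(Q = 1, R = 1e-12, x0 = y[1, 1])
  ks <- kalman_smoother(spec, params, y)
  expect_lt(max(abs(ks$xs - y)), 1e-4)
})

test_that("extract_states labels the habitat groups and warns on non-convergence", {
  sc <- flow_scenario(seed = 5, n_stations = 6, C = NULL)
  sim <- simulate_ssm(sc)
  spec <- ssm_spec(build_hypothesis_Z(sim$labels, "H6"), T = ncol(sim$y))
  fit <- fit_ml(spec, sim$y, method = "em", control = list(em_maxit = 2))
  expect_warning(st <- extract_states(fit), "non-converged")
  expect_equal(dim(st$mean), c(4, ncol(sim$y)))
  expect_setequal(rownames(st$mean), c("channel.midwater", "channel.otter",
                                       "shoal.midwater", "shoal.otter"))
  expect_true(all(st$se >= 0))
  # smoothed group states track the member-series means
  grp <- paste(sim$labels$lateral_habitat, sim$labels$gear, sep = ".")
  for (g in rownames(st$mean)) {
    gm <- colMeans(sim$y[grp == g, , drop = FALSE], na.rm = TRUE)
    expect_lt(max(abs(st$mean[g, ] - gm), na.rm = TRUE), 1)
  }
})
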