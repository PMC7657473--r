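test_that("piecewise mean functions match the stated forms", {
  # delta_S: sloped below the breakpoint, constant b above
  expect_equal(predict_delta_S(0, b = -2, c = -0.1, v_crit = 5), -1.5)
  expect_equal(predict_delta_S(5, b = -2, c = -0.1, v_crit = 5), -2)
  expect_equal(predict_delta_S(10, b = -2, c = -0.1, v_crit = 5), -2)
  # delta_A: constant b below, sloped above
  expect_equal(predict_delta_A(10, b = 0.1, c = 0.02, v_crit = 6), 0.18)
  expect_equal(predict_delta_A(3, b = 0.1, c = 0.02, v_crit = 6), 0.1)
  expect_equal(predict_delta_A(6, b = 0.1, c = 0.02, v_crit = 6), 0.1)
})

test_that("mean functions are continuous at the breakpoint", {
  for (vc in c(2, 5.5, 20)) {
    eps <- 1e-9
    for (f in list(predict_delta_S, predict_delta_A)) {
      lo <- f(vc - eps, b = 1, c = 0.3, v_crit = vc)
      hi <- f(vc + eps, b = 1, c = 0.3, v_crit = vc)
      at <- f(vc, b = 1, c = 0.3, v_crit = vc)
      expect_equal(lo, at, tolerance = 1e-6)
      expect_equal(hi, at, tolerance = 1e-6)
      # boundary convention is a measure-zero flag, value b either way
      expect_equal(f(vc, 1, 0.3, vc, boundary = "open"), 1)
      expect_equal(f(vc, 1, 0.3, vc, boundary = "closed"), 1)
    }
  }
})

test_that("the sampler recovers generating parameters of the delta_S form", {
  pars <- recovery_pars()[1:2, ]  # one user, two devices
  dat <- simulate_piecewise_data(400, pars, eps = 0.2, seed = 21)
  fit <- fit_piecewise(dat, outcome = "delta_S", variant = "no_user",
                       chains = 2, iter = 500, warmup = 500, seed = 9)
  td <- tidy(fit)
  for (i in 1:2) {
    g <- pars$device[i]
    for (tm in c("b", "c", "v_crit")) {
      truth <- pars[[c(b = "b", c = "c", v_crit = "v_crit")[tm]]][i]
      row <- td[td$term == tm & !is.na(td$group) & td$group == g, ]
      expect_lt(abs(row$estimate - truth), 3 * row$std.error)
    }
  }
  eps_row <- td[td$term == "epsilon", ]
  expect_lt(abs(eps_row$estimate - 0.2), 4 * eps_row$std.error)
  expect_true(all(td$conf.low <= td$conf.high))
  expect_true(all(is.finite(td$rhat)))
})

test_that("fits are exactly reproducible given a seed, and short runs are flagged", {
  pars <- recovery_pars()[1:2, ]
  dat <- simulate_piecewise_data(100, pars, eps = 0.3, seed = 3)
  # deliberately short chains: non-convergence must be flagged, not silent
  expect_warning(
    f1 <- fit_piecewise(dat, variant = "no_user", chains = 2,
                        iter = 200, warmup = 200, seed = 77),
    class = "protrack_convergence_warning"
  )
  f2 <- suppressWarnings(
    fit_piecewise(dat, variant = "no_user", chains = 2,
                  iter = 200, warmup = 200, seed = 77))
  expect_identical(f1$draws, f2$draws)
  expect_false(all(f1$diagnostics$converged))
})

test_that("with tiny noise the breakpoint posterior concentrates at the kink", {
  pars <- tibble::tibble(user = "U1", device = "mouse",
                         b = -2, c = -0.4, v_crit = 7)
  dat <- simulate_piecewise_data(300, pars, eps = 1e-3, seed = 5)
  fit <- fit_piecewise(dat, outcome = "delta_S", variant = "no_device",
                       chains = 2, iter = 500, warmup = 500, seed = 2)
  td <- tidy(fit)
  vc_hat <- td$estimate[td$term == "v_crit"]
  # independent profile-likelihood grid search for the kink
  vc_grid <- grid_search_vcrit(dat$V, dat$delta_S,
                               seq(0.5, 22.5, by = 0.05))
  expect_equal(vc_hat, vc_grid, tolerance = 0.01)
  expect_equal(vc_hat, 7, tolerance = 0.01)
  expect_lt(td$std.error[td$term == "v_crit"], 0.05)
})

test_that("groups with different parameters separate in the posterior", {
  pars <- recovery_pars()
  dat <- simulate_piecewise_data(300, pars, eps = 0.15, seed = 13)
  fit <- fit_piecewise(dat, outcome = "delta_S", variant = "full",
                       chains = 2, iter = 500, warmup = 500, seed = 4)
  td <- tidy(fit)
  for (i in seq_len(nrow(pars))) {
    g <- paste(pars$user[i], pars$device[i], sep = ":")
    row <- td[td$term == "b" & !is.na(td$group) & td$group == g, ]
    expect_gt(pars$b[i], row$conf.low)
    expect_lt(pars$b[i], row$conf.high)
  }
  # the most different plateaus do not share an interval
  b1 <- td[td$term == "b" & !is.na(td$group) & td$group == "U1:pen", ]
  b2 <- td[td$term == "b" & !is.na(td$group) & td$group == "U2:mouse", ]
  expect_gt(b1$conf.low, b2$conf.high)
})

test_that("delta_A fits carry the slope above the breakpoint", {
  pars <- tibble::tibble(user = "U1", device = "mouse",
                         b = 0.15, c = 0.012, v_crit = 6)
  dat <- simulate_piecewise_data(600, pars, eps = 0.03, seed = 8,
                                 outcome = "delta_A")
  fit <- fit_piecewise(dat, outcome = "delta_A", variant = "no_device",
                       chains = 2, iter = 500, warmup = 500, seed = 6)
  td <- tidy(fit)
  expect_lt(abs(td$estimate[td$term == "b"] - 0.15),
            3 * td$std.error[td$term == "b"])
  expect_lt(abs(td$estimate[td$term == "v_crit"] - 6),
            3 * td$std.error[td$term == "v_crit"])
  expect_gt(td$estimate[td$term == "c"], 0)
})

test_that("information criteria and comparison behave consistently", {
  pars <- recovery_pars()[c(1, 3), ]  # two users, one device
  dat <- simulate_piecewise_data(150, pars, eps = 0.2, seed = 17)
  fit <- suppressWarnings(
    fit_piecewise(dat, variant = "no_device", chains = 2,
                  iter = 400, warmup = 400, seed = 3))
  w <- waic(fit)
  l <- psis_loo(fit)
  # a model compared with itself has zero WAIC difference
  cmp <- compare_fits(list(a = fit, b = fit))
  expect_equal(cmp$table$d_waic, c(0, 0))
  expect_equal(cmp$table$se_d_waic, c(0, 0))
  # WAIC and LOO estimate the same quantity at this scale
  expect_equal(w$elpd_waic, l$elpd_loo, tolerance = 0.02 * abs(l$elpd_loo))
  expect_true(all(is.finite(l$pointwise$k_hat) | is.na(l$pointwise$k_hat)))
  # glance carries the criteria
  g <- glance(fit)
  expect_equal(g$waic, w$waic)
  expect_identical(g$nobs, nrow(dat))
  # mismatched data are refused
  dat2 <- simulate_piecewise_data(150, pars, eps = 0.2, seed = 18)
  fit2 <- suppressWarnings(
    fit_piecewise(dat2, variant = "no_device", chains = 2,
                  iter = 400, warmup = 400, seed = 3))
  expect_error(compare_fits(list(a = fit, b = fit2)),
               class = "protrack_comparison_error")
})

test_that("posterior mean curves stay continuous for every draw", {
  pars <- recovery_pars()[1:2, ]
  dat <- simulate_piecewise_data(120, pars, eps = 0.2, seed = 30)
  fit <- suppressWarnings(
    fit_piecewise(dat, variant = "no_user", chains = 1,
                  iter = 100, warmup = 200, seed = 12))
  b <- fit$draws[, "b[1]"]; cc <- fit$draws[, "c[1]"]
  vc <- fit$draws[, "vc[1]"]
  for (s in seq(1, length(b), by = 10)) {
    lo <- predict_delta_S(vc[s] - 1e-9, b[s], cc[s], vc[s])
    hi <- predict_delta_S(vc[s] + 1e-9, b[s], cc[s], vc[s])
    expect_equal(lo, hi, tolerance = 1e-6)
  }
})
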