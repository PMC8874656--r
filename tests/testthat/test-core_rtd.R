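# Core RTD mathematics: densities, normalization, moments, convolution.

test_that("normalize_to_E divides by the trapezoid integral", {
  # rectangular pulse of height 2 on [0, 5]: flat density 0.2
  g <- time_grid(0, 0.5, 11)
  e <- normalize_to_E(concentration_trace(g, rep(2, 11)))
  expect_equal(e$density, rep(0.2, 11))

  # idempotence: a curve already integrating to 1 is unchanged
  tr2 <- concentration_trace(g, e$density)
  expect_equal(normalize_to_E(tr2)$density, e$density)

  # triangle peaking at 4 at t = 10 over [0, 20]: brute-force integral 40
  gt <- time_grid(0, 1, 21)
  tt <- grid_times(gt)
  v <- ifelse(tt <= 10, 4 * tt / 10, 4 * (20 - tt) / 10)
  w <- c(0.5, rep(1, 19), 0.5)
  expect_equal(sum(w * v), 40)           # oracle: direct weighted summation
  e3 <- normalize_to_E(concentration_trace(gt, v))
  expect_equal(max(e3$density), 0.1)
  expect_equal(tt[which.max(e3$density)], 10)

  expect_error(normalize_to_E(concentration_trace(gt, rep(0, 21))),
               "non-positive")
})

test_that("baseline handling subtracts a constant or a pre-pulse mean", {
  g <- time_grid(0, 1, 201)
  tt <- grid_times(g)
  pulse <- ifelse(tt >= 50 & tt <= 60, 5, 0)
  tr <- concentration_trace(g, 100 + pulse)
  e_ref <- normalize_to_E(concentration_trace(g, pulse))
  expect_equal(normalize_to_E(tr, baseline = 100)$density, e_ref$density)
  expect_equal(normalize_to_E(tr, baseline_window = 30)$density,
               e_ref$density, tolerance = 1e-12)
})

test_that("mrt_of_curve is the first moment", {
  g <- time_grid(0, 0.5, 11)
  e <- et_curve(g, rep(0.2, 11))
  expect_equal(mrt_of_curve(e), 2.5)

  # delay + two equal tanks: mean is theta + 2 tau
  p <- rtd_params(tau_tank = 5, theta = 10)
  expect_equal(mrt_of_curve(e_unit(p, time_grid(0, 0.1, 1201))), 20,
               tolerance = 0.1 / 20)

  # Erlang-2 (theta = 0), tau = 104.5: closed form 2 tau = 209
  e2 <- e_unit(rtd_params(104.5, 0), time_grid(0, 0.1, 20001))
  expect_equal(mrt_of_curve(e2), 209, tolerance = 0.2 / 209)

  expect_error(mrt_of_curve(et_curve(g, rep(0.1, 11), normalized = FALSE)),
               "normalize")
})

test_that("e_pfr apportions the delta so the discrete mean equals theta", {
  g <- time_grid(0, 1, 30)
  expect_equal(e_pfr(0, g)$density[1L], 2)       # end node, weight step/2
  expect_equal(which(e_pfr(0, g)$density > 0), 1L)

  on_node <- e_pfr(7, g)
  expect_equal(on_node$density[8L], 1)           # 1/step at the node
  expect_equal(sum(on_node$density > 0), 1L)

  mid <- e_pfr(7.5, g)
  expect_equal(sum(mid$density > 0), 2L)
  w <- rep(1, 30); w[c(1, 30)] <- 0.5
  expect_equal(sum(w * grid_times(g) * mid$density), 7.5)  # brute-force mean
  expect_equal(mrt_of_curve(mid), 7.5)

  expect_error(e_pfr(100, g), "outside the grid")
})

test_that("e_cstr is the exponential density with mean tau", {
  g <- time_grid(0, 1, 1001)
  expect_equal(e_cstr(100, g)$density[1L], 0.01, tolerance = 1e-4)
  expect_equal(mrt_of_curve(e_cstr(50, g)), 50, tolerance = 0.1 / 50)
  gf <- time_grid(0, 0.001, 20001)
  expect_equal(mrt_of_curve(e_cstr(1, gf)), 1, tolerance = 0.001)
  expect_error(e_cstr(-1, g), "tau")
})

test_that("convolve_rtd: identity element, Erlang shape, MRT additivity", {
  g <- time_grid(0, 1, 1200)
  e <- e_unit(params_from_mrt_r(100, 0.4), g)
  expect_equal(convolve_rtd(e, e_pfr(0, g))$density, e$density,
               tolerance = 1e-12)

  # two equal tanks convolved = Erlang-2 = delay model with theta 0
  two <- convolve_rtd(e_cstr(50, g), e_cstr(50, g))
  erl <- e_unit(rtd_params(50, 0), g)
  expect_lt(max(abs(two$density - erl$density)), 1e-3)
  expect_equal(grid_times(g)[which.max(two$density)], 50, tolerance = 1)

  g2 <- time_grid(0, 1, 1500)
  conv <- convolve_rtd(e_cstr(30, g2), e_cstr(70, g2))
  expect_equal(mrt_of_curve(conv), 100, tolerance = 0.2 / 100)

  expect_error(convolve_rtd(e, e_cstr(30, g2)), "identical grid")
})

test_that("e_unit: support, mode, and closed-form mean", {
  p <- rtd_params(tau_tank = 5, theta = 10)
  g <- time_grid(0, 0.5, 301)
  e <- e_unit(p, g)
  tt <- grid_times(g)
  expect_true(all(e$density[tt < 10] == 0))
  expect_equal(tt[which.max(e$density)], 15)   # mode at theta + tau

  # parameters consistent with a feed-frame MRT of 292.5 s at R = 0.389
  e2 <- e_unit(rtd_params(64.0, 164.5), time_grid(0, 1, 1301))
  expect_equal(mrt_of_curve(e2), 292.5, tolerance = 0.3 / 292.5)

  expect_error(e_unit(rtd_params(5, 10), time_grid(0, 1, 9)), "exceeds")
  expect_warning(e_unit(rtd_params(5, 1), time_grid(0, 1, 31)), "truncated")
})

test_that("e_unit_general: unequal tanks, mean theta + tau1 + tau2", {
  g <- time_grid(0, 0.25, 4001)
  p <- general_two_tank_params(tau1 = 60, tau2 = 25, theta = 40)
  e <- e_unit_general(p, g)
  tt <- grid_times(g)
  expect_true(all(e$density[tt < 40] == 0))
  expect_equal(mrt_of_curve(e), 40 + 60 + 25, tolerance = 1e-3)

  # near-equal tanks approach the equal-tank model at matched mean
  pg <- general_two_tank_params(tau1 = 50.05, tau2 = 49.95, theta = 0)
  eg <- e_unit_general(pg, g)
  eu <- e_unit(rtd_params(50, 0), g)
  expect_lt(max(abs(eg$density - eu$density)) / max(eu$density), 0.01)

  expect_error(general_two_tank_params(10, 10, 0), "tau1 > tau2")
})

test_that("MRT/ratio algebra: forward, inverse, and error propagation", {
  expect_equal(mrt_from_tau_r(64.0, 0.389), 292.5, tolerance = 0.1 / 292.5)
  expect_equal(mrt_from_tau_r(1, 1e9), 2, tolerance = 1e-8)
  expect_equal(mrt_from_tau_r(48.2, 0.378), 224, tolerance = 0.5 / 224)
  expect_error(mrt_from_tau_r(1, -1), "r")

  p <- params_from_mrt_r(292.5, 0.389)
  expect_equal(p$tau_tank, 64.0, tolerance = 0.1 / 64)
  expect_equal(p$theta, 164.5, tolerance = 0.1 / 164.5)
  pl <- params_from_mrt_r(100, 1e9)
  expect_equal(pl$theta, 0, tolerance = 1e-6)
  expect_equal(pl$tau_tank, 50, tolerance = 1e-6)
  expect_equal(mrt_from_tau_r(8.59, 0.378), 39.9, tolerance = 0.1 / 39.9)

  # propagation limits
  expect_equal(epsilon_mrt(1, 1e9, eps_tau = 3, eps_r = 0), 6,
               tolerance = 1e-8)
  expect_equal(epsilon_mrt(10, 0.5, 0, 0), 0)
  tau <- 48.2; r <- 0.378; et <- 1.0; er <- 0.01
  direct <- sqrt((2 + 1 / r)^2 * et^2 + (tau / r^2)^2 * er^2)
  expect_equal(epsilon_mrt(tau, r, et, er), direct)
  expect_error(epsilon_mrt(1, 1, -1, 0), "eps")
})

test_that("property: model densities normalize and obey the mean identity", {
  set.seed(42)
  for (i in 1:20) {
    tau <- runif(1, 5, 120)
    r <- exp(runif(1, log(0.05), log(50)))
    p <- params_from_mrt_r(mrt_from_tau_r(tau, r), r)
    g <- time_grid(0, 1, ceiling(p$theta + 15 * tau) + 1)
    e <- suppressWarnings(e_unit(p, g))
    expect_equal(sum(rtdcontrol:::trapz_weights(g) * e$density), 1,
                 tolerance = 1e-9)
    expect_equal(mrt_of_curve(e), p$theta + 2 * tau,
                 tolerance = 1e-3)
  }
})

test_that("property: convolution is associative and MRT-additive", {
  set.seed(7)
  g <- time_grid(0, 1, 2000)
  for (i in 1:8) {
    taus <- runif(3, 10, 60)
    es <- lapply(taus, function(tau) {
      suppressWarnings(e_unit(params_from_mrt_r(mrt_from_tau_r(tau, 0.5), 0.5), g))
    })
    left <- convolve_rtd(convolve_rtd(es[[1]], es[[2]]), es[[3]])
    right <- convolve_rtd(es[[1]], convolve_rtd(es[[2]], es[[3]]))
    expect_lt(max(abs(left$density - right$density)), 1e-6)
    expect_lt(abs(mrt_of_curve(convolve_rtd(es[[1]], es[[2]])) -
                    mrt_of_curve(es[[1]]) - mrt_of_curve(es[[2]])),
              2 * g$step)
  }
})

test_that("property: params_from_mrt_r inverts mrt_from_tau_r", {
  set.seed(11)
  for (i in 1:25) {
    tau <- runif(1, 0.5, 500)
    r <- exp(runif(1, log(1e-3), log(1e5)))
    mrt <- mrt_from_tau_r(tau, r)
    p <- params_from_mrt_r(mrt, r)
    expect_equal(p$tau_tank, tau, tolerance = 1e-9)
    expect_equal(mrt_from_tau_r(p$tau_tank, r), mrt, tolerance = 1e-9)
    expect_equal(p$mrt, p$theta + 2 * p$tau_tank, tolerance = 1e-9)
  }
})
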