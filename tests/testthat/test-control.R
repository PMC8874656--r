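# Downstream prediction, dampability, and rejection limits.

kernel_15 <- function() {
  build_system_kernel(params_from_mrt_r(198, reference_r("blender1")),
                      params_from_mrt_r(137, reference_r("blender2")),
                      params_from_mrt_r(292.5, reference_r("feedframe")))
}

test_that("system kernel MRT is the sum of unit MRTs and order-invariant", {
  k <- kernel_15()
  expect_equal(mrt_of_curve(k$kernel), 198 + 137 + 292.5, tolerance = 2 / 627.5)

  b1 <- params_from_mrt_r(57, reference_r("blender1"))
  b2 <- params_from_mrt_r(39.9, reference_r("blender2"))
  ff <- params_from_mrt_r(68.5, reference_r("feedframe"))
  g <- default_grid(b1, b2, ff)
  ka <- build_system_kernel(b1, b2, ff, g)
  kb <- build_system_kernel(ff, b1, b2, g)
  expect_lt(max(abs(ka$kernel$density - kb$kernel$density)), 1e-9)

  expect_error(build_system_kernel(b1, b2, ff, time_grid(0, 1, 20)),
               "total delay")
})

test_that("predict_downstream has unit steady-state gain and delta response", {
  k <- kernel_15()
  n <- k$grid$n_points
  flat <- concentration_trace(k$grid, rep(100, n))
  out <- predict_downstream(flat, k, warmup = "keep")
  expect_equal(out$value[n], 100, tolerance = 0.1 / 100)

  # masked warm-up: NA before the kernel has filled, steady after
  masked <- predict_downstream(flat, k)
  expect_true(anyNA(masked$value))
  expect_equal(masked$value[n], 100, tolerance = 0.1 / 100)
  expect_gt(attr(masked, "warmup_end"), mrt_of_curve(k$kernel))

  # an impulse reproduces the kernel shape, scaled
  imp <- numeric(n); j <- 5L; imp[j] <- 42
  outi <- predict_downstream(concentration_trace(k$grid, imp), k,
                             warmup = "keep")
  expected <- 42 * k$grid$step * k$kernel$density
  idx <- seq(j + 2L, n)   # past the shifted edge node
  expect_equal(outi$value[idx], expected[idx - j + 1L], tolerance = 1e-9)
})

test_that("step response crosses 10/50/90% at the kernel CDF inverse", {
  k <- kernel_15()
  tt <- grid_times(k$grid)
  cdf <- curve_cdf(k$kernel)
  qf <- function(p) tt[which(cdf >= p)[1L]]
  n <- k$grid$n_points
  # step from 100 to 115 %LC only after the startup transient has passed
  t0 <- ceiling(qf(0.9999))
  g2 <- time_grid(0, 1, n + 2000L)
  gt2 <- grid_times(g2)
  v2 <- ifelse(gt2 < t0, 100, 115)
  k2 <- build_system_kernel(k$units$blender1, k$units$blender2,
                            k$units$feedframe, g2)
  out <- predict_downstream(concentration_trace(g2, v2), k2,
                            warmup = "keep")
  frac <- (out$value - 100) / 15
  for (p in c(0.1, 0.5, 0.9)) {
    t_cross <- gt2[which(frac >= p & gt2 >= t0)[1L]] - t0
    expect_lt(abs(t_cross - qf(p)), 5)
  }
})

test_that("max_outlet_deviation: limits and a brute-force window oracle", {
  k <- kernel_15()
  span <- grid_end(k$grid)
  expect_equal(max_outlet_deviation(k, disturbance_spec(30, 10 * span)), 30,
               tolerance = 1e-6)
  expect_lt(max_outlet_deviation(k, disturbance_spec(30, 0.01)), 0.1)

  # Erlang-2 kernel (high-ratio blender at 15 kg/h, 180 rpm): MRT 209 s
  tau <- 209 / (2 + 1 / 2.03e4)
  kb <- suppressWarnings(e_unit(params_from_mrt_r(209, 2.03e4),
                                time_grid(0, 1, 2500)))
  got <- max_outlet_deviation(kb, disturbance_spec(30, 50))
  # oracle: analytic Erlang-2 CDF, exhaustive window search on a fine grid
  Ferl <- function(t) ifelse(t < 0, 0, 1 - (1 + t / tau) * exp(-t / tau))
  tfine <- seq(0, 2500, by = 0.1)
  oracle <- 30 * max(Ferl(tfine) - Ferl(tfine - 50))
  expect_equal(got, oracle, tolerance = 0.01)
  expect_equal(got, 5.2, tolerance = 0.2 / 5.2)

  # linear in amplitude, non-decreasing in duration
  expect_equal(max_outlet_deviation(kb, disturbance_spec(60, 50)), 2 * got)
  devs <- vapply(c(10, 50, 100, 400), function(d) {
    max_outlet_deviation(kb, disturbance_spec(30, d))
  }, 0)
  expect_true(all(diff(devs) >= 0))
})

test_that("funnel region is monotone in amplitude, duration, and MRT", {
  amps <- c(0, 5, 10, 20, 30)
  durs <- c(5, 20, 50, 100, 200, 500)
  small <- suppressWarnings(e_unit(params_from_mrt_r(60, 0.5),
                                   time_grid(0, 1, 2000)))
  large <- suppressWarnings(e_unit(params_from_mrt_r(300, 0.5),
                                   time_grid(0, 1, 2000)))
  fr_small <- funnel_region(small, amps, durs)
  fr_large <- funnel_region(large, amps, durs)

  expect_true(all(fr_small$inside[fr_small$amplitude == 0]))
  # if (a, T) is outside, every (a' >= a, T' >= T) is outside
  for (df in list(fr_small, fr_large)) {
    out <- df[!df$inside, ]
    for (i in seq_len(nrow(out))) {
      dom <- df[df$amplitude >= out$amplitude[i] &
                  df$duration >= out$duration[i], ]
      expect_true(all(!dom$inside))
    }
  }
  # longer-residence kernel dampens a superset of disturbances
  expect_true(all(fr_large$inside >= fr_small$inside))
})

test_that("rmsep matches its definition", {
  expect_equal(rmsep(rep(100, 10), rep(100, 10)), 0)
  expect_equal(rmsep(rep(102, 54), rep(100, 54)), 2)
  expect_equal(rmsep(c(3, -4), c(0, 0)), sqrt(25 / 2))
  expect_error(rmsep(1:3, 1:2), "equal-length")
})

test_that("rejection limits tighten symmetrically inside 85-115", {
  l0 <- rejection_limits(0, 0)
  expect_equal(c(l0$lower, l0$upper), c(85, 115))
  l6 <- rejection_limits(6, 0)
  expect_equal(l6$lower, 85 + 1.645 * 6)
  expect_equal(round(c(l6$lower, l6$upper), 2), c(94.87, 105.13))
  l34 <- rejection_limits(3, 4)
  expect_equal(c(l34$lower, l34$upper), c(93.225, 106.775))
  # symmetry about 100 for any feasible inputs
  for (args in list(c(1, 0), c(4, 2), c(0, 5.5))) {
    l <- rejection_limits(args[1], args[2])
    expect_equal(l$lower - 85, 115 - l$upper, tolerance = 1e-12)
  }
  expect_error(rejection_limits(10, 0), "cross")
  expect_warning(rejection_limits(6), "sigma_weight")
})

test_that("apply_rejection flags exactly the excursion samples", {
  g <- time_grid(0, 1, 100)
  v <- rep(100, 100); v[40:45] <- 107
  tr <- concentration_trace(g, v)
  lim <- rejection_limits(6, 0)
  fl <- apply_rejection(tr, lim)
  expect_equal(which(fl$reject), 40:45)
  expect_false(any(apply_rejection(concentration_trace(g, rep(100, 100)),
                                   lim)$reject))
  # tightened limits flag a superset of the specification limits
  wide <- rejection_limits(0, 0)
  expect_true(all(apply_rejection(tr, wide)$reject <= fl$reject))
  # masked (NA) samples are never flagged
  v[1:10] <- NA
  tr2 <- structure(list(grid = g, value = v), class = "concentration_trace")
  expect_false(any(apply_rejection(tr2, lim)$reject[1:10]))
})
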