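# Synthetic impulse campaigns, tablet sampling, and step-change validation.

test_that("a noise-free pulse round-trips to the generating density", {
  cond <- operating_condition(50, speed_b2 = 210)
  truth <- list(blender2 = params_from_mrt_r(55.4, reference_r("blender2")))
  ex <- gen_impulse("blender2", cond, truth, noise = noiseless())
  expect_s3_class(ex, "impulse_experiment")
  expect_equal(ex$tracer_mass, 30)     # Blender 2 pulses use 30 g
  E <- normalize_to_E(ex$trace)
  model <- suppressWarnings(e_unit(truth$blender2, ex$trace$grid))
  expect_lt(max(abs(E$density - model$density)), 1e-9)

  # tracer mass is conserved through the concentration scaling
  expect_equal(tracer_mass_recovered(ex$trace, 50), 30,
               tolerance = 0.01)

  expect_error(gen_impulse("blender1", cond, truth),
               "truth parameters for blender1")
})

test_that("generators are deterministic under a fixed seed", {
  cond <- operating_condition(25, speed_b2 = 210)
  truth <- list(blender2 = params_from_mrt_r(94.6, 0.378))
  n1 <- noise_model(nir_sigma = 2.6, seed = 99)
  a <- gen_impulse("blender2", cond, truth, noise = n1)
  b <- gen_impulse("blender2", cond, truth, noise = n1)
  expect_identical(a$trace$value, b$trace$value)
  c2 <- gen_impulse("blender2", cond, truth,
                    noise = noise_model(nir_sigma = 2.6, seed = 100))
  expect_false(identical(a$trace$value, c2$trace$value))

  d1 <- gen_campaign(campaign_design(flows = 90), seed = 12)
  d2 <- gen_campaign(campaign_design(flows = 90), seed = 12)
  expect_identical(lapply(d1, function(e) e$trace$value),
                   lapply(d2, function(e) e$trace$value))
})

test_that("tablet composites sample on cadence and average down the noise", {
  g <- time_grid(0, 1, 501)
  flat <- concentration_trace(g, rep(100, 501))
  s0 <- gen_tablet_samples(flat, cadence = 25, noise = noiseless())
  expect_equal(nrow(s0), 20L)
  expect_true(all(s0$value == 100))
  expect_error(gen_tablet_samples(flat, cadence = 1000), "span")

  # composite of 10 shrinks sigma by ~1/sqrt(10) (Monte Carlo)
  short <- concentration_trace(time_grid(0, 1, 51), rep(100, 51))
  set.seed(202)
  draws <- replicate(1000, {
    gen_tablet_samples(short, cadence = 50, composite_n = 10,
                       noise = noise_model(hplc_sigma = 1))$value
  })
  expect_equal(stats::sd(draws), 1 / sqrt(10), tolerance = 0.1)
})

test_that("the step-change protocol yields 54 samples and zero-noise RMSEP 0", {
  ds <- gen_step_validation(noise = noiseless(), seed = 1)
  expect_equal(nrow(ds), 54L)   # 3 flows x 3 steps x 3 time points x 2
  expect_equal(sort(unique(ds$mass_flow)), c(15, 50, 90))
  expect_equal(rmsep(ds$measured, ds$predicted), 0)
  rep0 <- validation_report(ds)
  expect_true(rep0$pass)
  expect_equal(rep0$n_samples, 54L)

  expect_error(gen_step_validation(steps = c(100, 120)), "85, 115")
})

test_that("validation RMSEP concentrates at the assay sigma (Monte Carlo)", {
  # reuse one set of kernels; only the assay noise varies per replicate
  kerns <- lapply(c(15, 50, 90), function(f) {
    tr <- rtdcontrol:::truth_for_row(list(mass_flow = f, speed_b1 = 315,
                                          speed_b2 = 210))
    build_system_kernel(tr$blender1, tr$blender2, tr$feedframe)
  })
  rs <- vapply(1:200, function(s) {
    ds <- gen_step_validation(kernels = kerns,
                              noise = noise_model(hplc_sigma = 1.4),
                              seed = s)
    rmsep(ds$measured, ds$predicted)
  }, 0)
  expect_equal(mean(rs), 1.4, tolerance = 0.1)
})

test_that("campaign fits recover the generating feed-frame surface", {
  exps <- gen_campaign(campaign_design(),
                       noise_model(nir_sigma = 2, hplc_sigma = 2),
                       seed = 31)
  fits <- deconvolution_sequence(exps, fast_control())

  truth <- reference_truth("blender2")
  m <- merge(truth, goodness_of_fit(fits$blender2),
             by = c("mass_flow", "speed"))
  expect_true(all(abs(m$mrt.y / m$mrt.x - 1) < 0.05))
  m1 <- merge(reference_truth("blender1"), goodness_of_fit(fits$blender1),
              by = c("mass_flow", "speed"))
  expect_true(all(abs(m1$mrt.y / m1$mrt.x - 1) < 0.05))
  gff <- goodness_of_fit(fits$feedframe)
  tff <- reference_truth("feedframe")
  expect_true(all(abs(sort(gff$mrt) / sort(tff$mrt) - 1) < 0.05))

  # end-to-end: refit feed-frame surface matches the generating surface
  obs <- gff; names(obs) <- c("mass_flow", "speed", "mrt", "eps")
  obs$eps <- pmax(obs$eps, 1e-6)
  surf <- fit_empirical(obs, "feedframe")
  gen_surf <- reference_constants()$feedframe
  for (f in c(15, 25, 50, 90)) {
    expect_equal(predict_mrt(surf, operating_condition(f)),
                 predict_mrt(gen_surf, operating_condition(f)),
                 tolerance = 0.05)
  }
})
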