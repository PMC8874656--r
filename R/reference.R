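#' Reference characterization values for the studied direct-compression line
#'
#' Regressed mean-residence-time tables, ratio constants and empirical
#' surface constants from the characterization of a GEA CDC-50 three-unit
#' line (Blender 1, Blender 2, tablet-press feed frame). These serve as
#' ground truth for the synthetic-data generators and as verification
#' fixtures for the empirical-surface routines.
#'
#' Units: mass flow kg/h, impeller speed rpm, MRT and its fit statistic
#' `eps` in seconds.
#'
#' @param unit One of `"blender1"`, `"blender2"`, `"feedframe"`.
#' @return `reference_mrt()`: a data frame with columns `mass_flow`,
#'   `speed` (NA for the feed frame), `mrt`, `eps`. `reference_r()`: the
#'   unit's shared ratio constant `R = tau_tank / theta`.
#'   `reference_constants()`: a list of [empirical_constants()] keyed by
#'   unit.
#' @examples
#' reference_mrt("feedframe")
#' reference_r("blender2")
#' @export
reference_mrt <- function(unit = c("blender1", "blender2", "feedframe")) {
  unit <- match.arg(unit)
  switch(unit,
    blender1 = data.frame(
      mass_flow = rep(c(15, 25, 50, 90), each = 3),
      speed     = rep(c(180, 315, 450), times = 4),
      mrt = c(209, 198, 91.0,
              106, 104, 66.0,
              90.5, 74.5, 56.6,
              70.8, 57.0, 39.0),
      eps = c(10.9, 6.10, 4.02,
              4.25, 2.26, 2.45,
              2.37, 1.34, 1.74,
              2.35, 1.07, 1.02)),
    blender2 = data.frame(
      mass_flow = rep(c(15, 25, 50, 90), each = 3),
      speed     = rep(c(150, 210, 300), times = 4),
      mrt = c(224, 137, 85.2,
              194, 94.6, 76.7,
              155, 55.4, 45.8,
              99.3, 39.9, 31.6),
      eps = c(12.6, 4.84, 3.41,
              10.3, 2.95, 3.16,
              6.13, 1.67, 1.55,
              4.17, 1.11, 1.02)),
    feedframe = data.frame(
      mass_flow = c(15, 25, 50, 90),
      speed = NA_real_,
      mrt = c(292.5, 145.0, 82.8, 68.5),
      eps = c(22.9, 14.8, 7.05, 4.29))
  )
}

#' @rdname reference_mrt
#' @export
reference_r <- function(unit = c("blender1", "blender2", "feedframe")) {
  unit <- match.arg(unit)
  c(blender1 = 2.03e4, blender2 = 0.378, feedframe = 0.389)[[unit]]
}

#' @rdname reference_mrt
#' @export
reference_constants <- function() {
  list(
    blender1 = empirical_constants("blender1", A = 4.65e2, B = 3.54e3,
                                   C = 3.49e5, D = 23.2),
    blender2 = empirical_constants("blender2", A = -2.70e2, B = 1.48e4,
                                   C = 4.12e5, D = -34.6),
    feedframe = empirical_constants("feedframe", D = 62.1, E = 5.19e4)
  )
}

#' Ground-truth unit parameters for synthetic campaigns
#'
#' Converts the reference MRT table of a unit to per-condition
#' [rtd_params()] via [params_from_mrt_r()] with the unit's shared ratio
#' constant.
#'
#' @inheritParams reference_mrt
#' @return A data frame with the reference columns plus `tau_tank`, `theta`.
#' @export
reference_truth <- function(unit = c("blender1", "blender2", "feedframe")) {
  unit <- match.arg(unit)
  tab <- reference_mrt(unit)
  r <- reference_r(unit)
  ps <- lapply(tab$mrt, params_from_mrt_r, r = r)
  tab$tau_tank <- vapply(ps, function(p) p$tau_tank, 0)
  tab$theta <- vapply(ps, function(p) p$theta, 0)
  tab$r <- r
  tab
}

#' Reference characterization packaged as a fit result
#'
#' Wraps [reference_truth()] in the `unit_fit_result` structure returned
#' by [fit_unit_joint()], so the reference parameters can serve as
#' known-upstream inputs to a deconvolution without running a
#' regression.
#'
#' @inheritParams reference_mrt
#' @return A `unit_fit_result`.
#' @export
reference_fit_result <- function(unit = c("blender1", "blender2",
                                          "feedframe")) {
  unit <- match.arg(unit)
  tab <- reference_truth(unit)
  per <- data.frame(mass_flow = tab$mass_flow, speed = tab$speed,
                    tau_tank = tab$tau_tank, theta = tab$theta,
                    mrt = tab$mrt, eps_tau = 0, eps_mrt = 0)
  structure(list(unit = unit, per_condition = per,
                 shared_r = reference_r(unit), eps_r = 0,
                 n_parameters = 2L * nrow(per) + 1L, residual_sse = 0,
                 n_conditions = nrow(per), n_residuals = NA_integer_),
            class = "unit_fit_result")
}
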