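#' Full-line residence-time kernel
#'
#' Convolution of the three unit densities (Blender 1, Blender 2, feed
#' frame) on a common grid: the impulse response of the whole line from
#' the feeder inlet to the tablet press outlet. Its mean residence time
#' is the sum of the unit MRTs.
#'
#' @param b1,b2,ff [rtd_params()] for the three units.
#' @param grid Optional [time_grid()]; defaults to [default_grid()] over
#'   the three parameter sets, and must span the total delay.
#' @return An object of class `system_kernel` with elements `units`,
#'   `grid`, `kernel` (an [et_curve()]).
#' @export
build_system_kernel <- function(b1, b2, ff, grid = NULL) {
  units <- list(blender1 = b1, blender2 = b2, feedframe = ff)
  if (is.null(grid)) grid <- default_grid(b1, b2, ff)
  theta_tot <- b1$theta + b2$theta + ff$theta
  if (theta_tot > grid_end(grid))
    stop(sprintf("build_system_kernel: grid ends at %g s, before the total delay %g s",
                 grid_end(grid), theta_tot), call. = FALSE)
  k <- convolve_rtd(convolve_rtd(suppressWarnings(e_unit(b1, grid)),
                                 suppressWarnings(e_unit(b2, grid))),
                    suppressWarnings(e_unit(ff, grid)))
  structure(list(units = units, grid = grid, kernel = k),
            class = "system_kernel")
}

#' @export
print.system_kernel <- function(x, ...) {
  cat(sprintf("<system_kernel> MRT %.4g s on %d x %g s grid (unit MRTs: %s)\n",
              mrt_of_curve(x$kernel), x$grid$n_points, x$grid$step,
              paste(sprintf("%.4g", vapply(x$units, function(p) p$mrt, 0)),
                    collapse = " + ")))
  invisible(x)
}

as_kernel_curve <- function(kernel) {
  if (inherits(kernel, "system_kernel")) kernel$kernel
  else if (inherits(kernel, "et_curve")) kernel
  else stop("expected a system_kernel or et_curve", call. = FALSE)
}

#' Predict downstream (tablet) concentration from a feeder trace
#'
#' Causal discrete convolution of the incoming API concentration with the
#' line's residence-time kernel. The normalized kernel has unit gain: a
#' constant input reproduces the same constant output once the startup
#' transient has passed. Output before the kernel has substantially
#' filled (its cumulative distribution reaching 99.9%) reflects the
#' unknown pre-run line content; by default those samples are masked NA.
#'
#' @param feeder A [concentration_trace()] on the kernel's grid step.
#' @param kernel A `system_kernel` (or bare [et_curve()]).
#' @param warmup `"mask"` (default) to set the startup transient to NA,
#'   `"keep"` to return raw convolution output everywhere.
#' @return A [concentration_trace()] on the feeder grid, with attribute
#'   `warmup_end` (seconds).
#' @export
predict_downstream <- function(feeder, kernel, warmup = c("mask", "keep")) {
  warmup <- match.arg(warmup)
  stopifnot(inherits(feeder, "concentration_trace"))
  k <- as_kernel_curve(kernel)
  if (abs(feeder$grid$step - k$grid$step) > 1e-9 * k$grid$step)
    stop(sprintf("predict_downstream: feeder step %g s does not match kernel step %g s",
                 feeder$grid$step, k$grid$step), call. = FALSE)
  n <- feeder$grid$n_points
  kd <- k$density
  kd[1L] <- kd[1L] / 2   # trapezoid-consistent edge (see convolve_rtd)
  full <- stats::convolve(feeder$value, rev(kd), type = "open")
  out <- full[seq_len(n)] * k$grid$step
  cdf <- curve_cdf(k)
  t_warm <- grid_times(k$grid)[which(cdf >= 0.999)[1L]]
  if (is.na(t_warm)) t_warm <- grid_end(k$grid)
  if (warmup == "mask") {
    tt <- grid_times(feeder$grid)
    out[tt - feeder$grid$start < t_warm] <- NA_real_
  }
  tr <- structure(list(grid = feeder$grid, value = out),
                  class = "concentration_trace")
  attr(tr, "warmup_end") <- t_warm
  tr
}

#' Rectangular inlet disturbance
#'
#' @param amplitude Signed disturbance amplitude in %LC (e.g. +30 or -30).
#' @param duration Disturbance duration in seconds (> 0).
#' @return An object of class `disturbance_spec`.
#' @export
disturbance_spec <- function(amplitude, duration) {
  if (!is.finite(duration) || duration <= 0)
    stop("disturbance_spec: duration must be > 0", call. = FALSE)
  structure(list(amplitude = amplitude, duration = duration,
                 shape = "rectangular"), class = "disturbance_spec")
}

#' Peak outlet deviation caused by a rectangular inlet disturbance
#'
#' For a linear time-invariant mixing system, a rectangular inlet
#' disturbance of amplitude a and duration T produces a peak outlet
#' deviation of `|a|` times the largest mass the kernel's cumulative
#' distribution F packs into any window of width T:
#' `|a| * max_t [F(t) - F(t - T)]`.
#'
#' @param kernel A `system_kernel` or [et_curve()] (a single unit's
#'   density is admitted for per-unit dampability maps).
#' @param disturbance A [disturbance_spec()].
#' @return Peak absolute outlet deviation in %LC.
#' @export
max_outlet_deviation <- function(kernel, disturbance) {
  stopifnot(inherits(disturbance, "disturbance_spec"))
  k <- as_kernel_curve(kernel)
  abs(disturbance$amplitude) * max_window_mass(k, disturbance$duration)
}

# largest kernel CDF mass in any window of width `duration`
max_window_mass <- function(k, duration) {
  tt <- grid_times(k$grid)
  cdf <- curve_cdf(k)
  f <- stats::approxfun(tt, cdf, yleft = 0, yright = cdf[length(cdf)])
  max(f(tt) - f(tt - duration))
}

#' Dampability (funnel) region over disturbance amplitude and duration
#'
#' Marks which rectangular inlet disturbances the mixing system
#' attenuates to an outlet concentration inside the quality limits
#' around 100 %LC. The region shrinks monotonically as amplitude or
#' duration grows, and a longer-residence kernel dampens a superset of
#' disturbances.
#'
#' @param kernel A `system_kernel` or [et_curve()].
#' @param amplitudes Numeric vector of disturbance amplitudes (%LC).
#' @param durations Numeric vector of disturbance durations (s).
#' @param limits Outlet limits in %LC, default `c(95, 105)`.
#' @return A data frame of class `funnel_region` with columns
#'   `amplitude`, `duration`, `deviation` (peak outlet deviation, %LC)
#'   and `inside` (logical).
#' @export
funnel_region <- function(kernel, amplitudes, durations,
                          limits = c(95, 105)) {
  if (length(amplitudes) == 0L || length(durations) == 0L)
    stop("funnel_region: amplitude and duration grids must be non-empty",
         call. = FALSE)
  k <- as_kernel_curve(kernel)
  wm <- vapply(durations, function(d) {
    if (d <= 0) 0 else max_window_mass(k, d)
  }, 0)
  g <- expand.grid(amplitude = amplitudes, duration = durations,
                   KEEP.OUT.ATTRS = FALSE)
  g$deviation <- abs(g$amplitude) * wm[match(g$duration, durations)]
  g$inside <- (100 + g$deviation) <= limits[2] &
    (100 - g$deviation) >= limits[1]
  class(g) <- c("funnel_region", "data.frame")
  attr(g, "limits") <- limits
  g
}

#' @export
plot.funnel_region <- function(x, ...) {
  a <- sort(unique(x$amplitude)); d <- sort(unique(x$duration))
  z <- matrix(x$inside[order(x$duration, x$amplitude)],
              nrow = length(a), ncol = length(d))
  graphics::image(a, d, z, col = c("firebrick", "forestgreen"),
                  xlab = "disturbance amplitude (%LC)",
                  ylab = "duration (s)", ...)
  invisible(x)
}

#' Root mean squared error of prediction
#'
#' `sqrt(sum((measured - predicted)^2) / N)` between tablet assay and
#' model-predicted concentration, in %LC.
#'
#' @param measured,predicted Equal-length numeric vectors (%LC).
#' @return RMSEP in %LC.
#' @export
rmsep <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 1L)
    stop("rmsep: need equal-length non-empty vectors", call. = FALSE)
  sqrt(mean((measured - predicted)^2))
}

#' Statistically tightened in-process rejection limits
#'
#' Pulls the 85/115 %LC specification limits inward by
#' `z * sqrt(RMSEP^2 + sigma_weight^2)` so that, with one-sided
#' confidence `pnorm(z)`, material predicted inside the tightened band
#' truly lies inside specification despite model prediction error and
#' tablet-weight variability.
#'
#' @param rmsep_acceptance Model RMSEP acceptance value in %LC (>= 0).
#' @param sigma_weight Individual tablet-weight variability in %LC
#'   (>= 0). Defaults to 0 with a warning, since it is line-specific.
#' @param z z-score of the one-sided confidence level (default 1.645,
#'   95%).
#' @return An object of class `rejection_limits` with `lower`, `upper`,
#'   `rmsep`, `sigma_weight`, `z`.
#' @examples
#' rejection_limits(6)           # (94.87, 105.13)
#' @export
rejection_limits <- function(rmsep_acceptance, sigma_weight = NULL,
                             z = 1.645) {
  if (is.null(sigma_weight)) {
    warning("rejection_limits: sigma_weight not supplied; assuming 0 ",
            "(no tablet-weight variance)", call. = FALSE)
    sigma_weight <- 0
  }
  if (rmsep_acceptance < 0 || sigma_weight < 0 || z < 0)
    stop("rejection_limits: inputs must be >= 0", call. = FALSE)
  tighten <- z * sqrt(rmsep_acceptance^2 + sigma_weight^2)
  lower <- 85 + tighten
  upper <- 115 - tighten
  if (lower >= upper)
    stop(sprintf(
      "rejection_limits: tightening term %.3g %%LC makes the limits cross; the model error is too large for a usable band",
      tighten), call. = FALSE)
  structure(list(lower = lower, upper = upper, rmsep = rmsep_acceptance,
                 sigma_weight = sigma_weight, z = z),
            class = "rejection_limits")
}

#' @export
print.rejection_limits <- function(x, ...) {
  cat(sprintf("<rejection_limits> [%.3f, %.3f] %%LC (RMSEP %.3g, sigma_w %.3g, z %.4g)\n",
              x$lower, x$upper, x$rmsep, x$sigma_weight, x$z))
  invisible(x)
}

#' Flag predicted material outside the rejection limits
#'
#' @param predicted A [concentration_trace()] of predicted tablet
#'   concentration; NA values (e.g. masked startup) are never flagged.
#' @param limits A [rejection_limits()].
#' @return A data frame with columns `time_s`, `predicted`, `reject`.
#' @export
apply_rejection <- function(predicted, limits) {
  stopifnot(inherits(predicted, "concentration_trace"),
            inherits(limits, "rejection_limits"))
  v <- predicted$value
  rej <- !is.na(v) & (v < limits$lower | v > limits$upper)
  data.frame(time_s = grid_times(predicted$grid), predicted = v,
             reject = rej)
}
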