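#' Per-unit RTD parameter set
#'
#' Each blending unit is modeled as a plug-flow delay of `theta` seconds
#' followed by two equal stirred tanks of mean residence time `tau_tank`
#' each. Derived quantities: the ratio `r_ratio = tau_tank / theta`
#' (back-mixing vs axial transport) and the unit mean residence time
#' `mrt = theta + 2 * tau_tank`. The `eps_*` fields carry fit statistics
#' (asymptotic standard errors) where available.
#'
#' @param tau_tank Tank mean residence time, seconds (> 0).
#' @param theta Plug-flow delay, seconds (>= 0).
#' @param eps_tau,eps_r,eps_mrt Optional fit statistics (defaults 0).
#' @return An object of class `rtd_params`.
#' @export
rtd_params <- function(tau_tank, theta, eps_tau = 0, eps_r = 0,
                       eps_mrt = NA_real_) {
  if (!is.finite(tau_tank) || tau_tank <= 0)
    stop("rtd_params: tau_tank must be > 0", call. = FALSE)
  if (!is.finite(theta) || theta < 0)
    stop("rtd_params: theta must be >= 0", call. = FALSE)
  if (eps_tau < 0 || eps_r < 0)
    stop("rtd_params: eps values must be >= 0", call. = FALSE)
  r <- if (theta > 0) tau_tank / theta else Inf
  mrt <- theta + 2 * tau_tank
  if (is.na(eps_mrt) && is.finite(r))
    eps_mrt <- epsilon_mrt(tau_tank, r, eps_tau, eps_r)
  structure(list(tau_tank = tau_tank, theta = theta, r_ratio = r,
                 mrt = mrt, eps_tau = eps_tau, eps_r = eps_r,
                 eps_mrt = eps_mrt),
            class = "rtd_params")
}

#' @export
print.rtd_params <- function(x, ...) {
  cat(sprintf("<rtd_params> tau=%.4g s, theta=%.4g s, R=%.4g, MRT=%.4g s\n",
              x$tau_tank, x$theta, x$r_ratio, x$mrt))
  invisible(x)
}

#' General two-tank parameter set (unequal tanks)
#'
#' The unconstrained delay + two-CSTR model with distinct tank sizes.
#' Requires `tau1 > tau2 > 0` to keep the parameterization identifiable.
#' Retained for completeness; the fitting machinery uses the equal-tank
#' form, whose parameters are better determined.
#'
#' @param tau1,tau2 Tank mean residence times in seconds, `tau1 > tau2 > 0`.
#' @param theta Plug-flow delay in seconds (>= 0).
#' @return An object of class `general_two_tank_params`.
#' @export
general_two_tank_params <- function(tau1, tau2, theta) {
  if (!(is.finite(tau1) && is.finite(tau2) && tau1 > tau2 && tau2 > 0))
    stop("general_two_tank_params: need tau1 > tau2 > 0", call. = FALSE)
  if (!is.finite(theta) || theta < 0)
    stop("general_two_tank_params: theta must be >= 0", call. = FALSE)
  structure(list(tau1 = tau1, tau2 = tau2, theta = theta),
            class = "general_two_tank_params")
}

#' Plug-flow (pure delay) residence-time density
#'
#' The continuous density is a Dirac delta at `theta`. On the discrete grid
#' the unit mass is apportioned linearly between the two nodes bracketing
#' `theta`, so that the discrete first moment equals `theta` exactly and
#' convolution with this kernel preserves mean residence time even on
#' coarse grids.
#'
#' @param theta Delay in seconds (>= 0, within the grid).
#' @param grid A [time_grid()].
#' @return An [et_curve()].
#' @export
e_pfr <- function(theta, grid) {
  stopifnot(inherits(grid, "time_grid"))
  if (!is.finite(theta) || theta < 0)
    stop("e_pfr: theta must be >= 0", call. = FALSE)
  tt <- grid_times(grid)
  if (theta < tt[1L] - 1e-12 || theta > tt[length(tt)] + 1e-12)
    stop(sprintf("e_pfr: theta = %g s lies outside the grid [%g, %g]",
                 theta, tt[1L], tt[length(tt)]), call. = FALSE)
  w <- trapz_weights(grid)
  d <- numeric(grid$n_points)
  j <- min(max(1L, findInterval(theta, tt)), grid$n_points - 1L)
  a <- (tt[j + 1L] - theta) / grid$step    # mass fraction on the left node
  a <- min(max(a, 0), 1)
  d[j] <- a / w[j]
  d[j + 1L] <- d[j + 1L] + (1 - a) / w[j + 1L]
  et_curve(grid, d, normalized = TRUE, tol = 1e-9)
}

#' Ideal stirred-tank (CSTR) residence-time density
#'
#' Exponential density `exp(-t/tau)/tau`, renormalized over the finite grid.
#'
#' @param tau Tank mean residence time in seconds (> 0).
#' @param grid A [time_grid()]; should span at least ~10 tau for the
#'   truncated tail to be negligible.
#' @return An [et_curve()].
#' @export
e_cstr <- function(tau, grid) {
  stopifnot(inherits(grid, "time_grid"))
  if (!is.finite(tau) || tau <= 0)
    stop("e_cstr: tau must be > 0", call. = FALSE)
  tt <- grid_times(grid)
  d <- exp(-tt / tau) / tau
  renormalize(et_curve(grid, d, normalized = FALSE))
}

#' Delay + two-equal-tank residence-time density for one blending unit
#'
#' Density `(t - theta) * exp(-(t - theta)/tau) / tau^2` for `t >= theta`,
#' zero before the delay: an Erlang-2 density shifted by `theta`. This is
#' the working model for each blending unit (both blenders and the feed
#' frame). The mode sits at `theta + tau` and the mean at `theta + 2 tau`.
#'
#' @param params An [rtd_params()] (or a list with `tau_tank`, `theta`).
#' @param grid A [time_grid()]. If the grid ends before `theta + 10 tau`
#'   a truncation warning is emitted; mass is renormalized either way.
#' @return An [et_curve()].
#' @export
e_unit <- function(params, grid) {
  stopifnot(inherits(grid, "time_grid"))
  tau <- params$tau_tank
  theta <- params$theta
  if (!is.finite(tau) || tau <= 0) stop("e_unit: tau_tank must be > 0",
                                        call. = FALSE)
  if (!is.finite(theta) || theta < 0) stop("e_unit: theta must be >= 0",
                                           call. = FALSE)
  if (theta > grid_end(grid))
    stop(sprintf("e_unit: delay theta = %g s exceeds the grid end %g s",
                 theta, grid_end(grid)), call. = FALSE)
  if (grid_end(grid) < theta + 10 * tau)
    warning(sprintf(
      "e_unit: grid ends at %g s, short of theta + 10*tau = %g s; tail truncated",
      grid_end(grid), theta + 10 * tau), call. = FALSE)
  tt <- grid_times(grid)
  s <- tt - theta
  d <- ifelse(s >= 0, s * exp(-s / tau) / tau^2, 0)
  renormalize(et_curve(grid, d, normalized = FALSE))
}

#' Delay + two-unequal-tank residence-time density
#'
#' The general form with distinct tank sizes:
#' `(exp(-(t-theta)/tau1) - exp(-(t-theta)/tau2)) / (tau1 - tau2)` for
#' `t >= theta`. Its mean is `theta + tau1 + tau2`.
#'
#' @param params A [general_two_tank_params()].
#' @param grid A [time_grid()].
#' @return An [et_curve()].
#' @export
e_unit_general <- function(params, grid) {
  stopifnot(inherits(params, "general_two_tank_params"),
            inherits(grid, "time_grid"))
  tt <- grid_times(grid)
  s <- tt - params$theta
  d <- ifelse(s >= 0,
              (exp(-s / params$tau1) - exp(-s / params$tau2)) /
                (params$tau1 - params$tau2),
              0)
  renormalize(et_curve(grid, d, normalized = FALSE))
}

#' Convolve two residence-time densities
#'
#' Discrete convolution scaled by the grid step (computed via FFT),
#' truncated to the common grid and renormalized to absorb truncation
#' loss. Mean residence times add under convolution.
#'
#' @param e1,e2 [et_curve()] objects on identical uniform grids starting
#'   at t = 0.
#' @return An [et_curve()] on the same grid.
#' @export
convolve_rtd <- function(e1, e2) {
  stopifnot(inherits(e1, "et_curve"), inherits(e2, "et_curve"))
  if (!same_grid(e1$grid, e2$grid))
    stop("convolve_rtd: curves must share an identical grid", call. = FALSE)
  if (abs(e1$grid$start) > 1e-9)
    stop("convolve_rtd: grids must start at t = 0", call. = FALSE)
  n <- e1$grid$n_points
  # trapezoid-consistent discrete convolution: halving the t = 0 samples
  # makes step * sum equal the trapezoid rule for the convolution integral,
  # so quadrature bias is O(step^2) even for densities nonzero at t = 0
  a1 <- e1$density; a1[1L] <- a1[1L] / 2
  a2 <- e2$density; a2[1L] <- a2[1L] / 2
  full <- stats::convolve(a1, rev(a2), type = "open")
  d <- full[seq_len(n)] * e1$grid$step
  d[1L] <- 0  # zero-width integral
  d[abs(d) < .Machine$double.eps] <- 0
  d <- pmax(d, 0)   # FFT round-off can leave tiny negatives
  renormalize(et_curve(e1$grid, d, normalized = FALSE))
}

#' Mean residence time from tank time and ratio constant
#'
#' With the ratio constant `R = tau_tank / theta` shared across operating
#' conditions, the unit mean residence time is `tau * (2 + 1/R)`.
#'
#' @param tau Tank mean residence time, seconds (> 0).
#' @param r Ratio constant (> 0).
#' @return MRT in seconds.
#' @seealso [params_from_mrt_r()] for the inversion.
#' @export
mrt_from_tau_r <- function(tau, r) {
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("mrt_from_tau_r: tau must be > 0", call. = FALSE)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("mrt_from_tau_r: r must be > 0", call. = FALSE)
  tau * (2 + 1 / r)
}

#' Invert a mean residence time and ratio constant to unit parameters
#'
#' Solves `mrt = tau * (2 + 1/r)` for `tau` and sets `theta = tau / r`.
#' Round-trips with [mrt_from_tau_r()] to machine precision.
#'
#' @param mrt Unit mean residence time, seconds (> 0).
#' @param r Ratio constant (> 0).
#' @param eps_tau,eps_r Optional fit statistics forwarded to the result.
#' @return An [rtd_params()].
#' @export
params_from_mrt_r <- function(mrt, r, eps_tau = 0, eps_r = 0) {
  if (!is.finite(mrt) || mrt <= 0)
    stop("params_from_mrt_r: mrt must be > 0", call. = FALSE)
  if (!is.finite(r) || r <= 0)
    stop("params_from_mrt_r: r must be > 0", call. = FALSE)
  tau <- mrt / (2 + 1 / r)
  rtd_params(tau_tank = tau, theta = tau / r, eps_tau = eps_tau,
             eps_r = eps_r)
}

#' Propagate parameter fit statistics to the mean residence time
#'
#' First-order error propagation through `MRT = tau * (2 + 1/R)`:
#' `eps_MRT = sqrt((2 + 1/R)^2 eps_tau^2 + (tau/R^2)^2 eps_R^2)`.
#'
#' @param tau Tank mean residence time (> 0).
#' @param r Ratio constant (> 0).
#' @param eps_tau,eps_r Fit statistics for `tau` and `R` (>= 0).
#' @return Propagated MRT statistic in seconds.
#' @export
epsilon_mrt <- function(tau, r, eps_tau, eps_r) {
  if (any(tau <= 0) || any(r <= 0))
    stop("epsilon_mrt: tau and r must be > 0", call. = FALSE)
  if (any(eps_tau < 0) || any(eps_r < 0))
    stop("epsilon_mrt: eps values must be >= 0", call. = FALSE)
  sqrt((2 + 1 / r)^2 * eps_tau^2 + (tau / r^2)^2 * eps_r^2)
}

#' Default grid for a parameter set
#'
#' A grid from 0 spanning the total delay plus 15 total tank times, so the
#' truncated tail mass is below ~1e-4.
#'
#' @param ... One or more [rtd_params()] whose kernel will live on the grid.
#' @param step Grid step in seconds (default 1, the feeder/NIR cadence).
#' @return A [time_grid()].
#' @export
default_grid <- function(..., step = 1) {
  ps <- list(...)
  theta_tot <- sum(vapply(ps, function(p) p$theta, 0))
  tau_tot <- sum(vapply(ps, function(p) p$tau_tank, 0))
  span <- theta_tot + 15 * tau_tot
  n <- max(2L, ceiling(span / step) + 1L)
  time_grid(start = 0, step = step, n_points = n)
}
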