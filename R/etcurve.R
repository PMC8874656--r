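#' Residence-time density sampled on a time grid
#'
#' An `et_curve` holds the residence-time probability density E(t) (units
#' 1/second) sampled on a uniform [time_grid()]. Densities produced by the
#' model constructors integrate to 1 by trapezoid quadrature; measured curves
#' derived from noisy concentration data may carry small negative excursions
#' and are admitted with `allow_negative = TRUE`.
#'
#' @param grid A [time_grid()].
#' @param density Numeric vector of density values, one per grid node.
#' @param normalized If `TRUE` (default), check that the trapezoid integral
#'   is 1 within `tol`.
#' @param tol Tolerance on the integral check; use a looser value (e.g. 1e-3)
#'   for curves truncated on a finite grid.
#' @param allow_negative Admit negative density values (measured noisy data).
#' @return An object of class `et_curve`.
#' @seealso [normalize_to_E()], [mrt_of_curve()], [e_unit()]
#' @export
et_curve <- function(grid, density, normalized = TRUE, tol = 1e-6,
                     allow_negative = FALSE) {
  stopifnot(inherits(grid, "time_grid"))
  if (length(density) != grid$n_points)
    stop("et_curve: density length must equal grid n_points", call. = FALSE)
  if (!all(is.finite(density)))
    stop("et_curve: density values must be finite", call. = FALSE)
  if (!allow_negative && any(density < -1e-12 * max(abs(density), 1)))
    stop("et_curve: density values must be non-negative", call. = FALSE)
  obj <- structure(list(grid = grid, density = as.numeric(density)),
                   class = "et_curve")
  if (normalized) {
    int <- curve_integral(obj)
    if (abs(int - 1) > tol)
      stop(sprintf("et_curve: density integrates to %.6g, not 1 (tol %g)",
                   int, tol), call. = FALSE)
  }
  obj
}

#' Time-stamped concentration trace
#'
#' Concentrations are expressed throughout in percent of the target label
#' claim (%LC), 100 = on target.
#'
#' @param grid A [time_grid()].
#' @param value Numeric vector of concentrations (%LC), one per grid node.
#' @return An object of class `concentration_trace`.
#' @export
concentration_trace <- function(grid, value) {
  stopifnot(inherits(grid, "time_grid"))
  if (length(value) != grid$n_points)
    stop("concentration_trace: value length must equal grid n_points",
         call. = FALSE)
  if (!all(is.finite(value)))
    stop("concentration_trace: values must be finite", call. = FALSE)
  structure(list(grid = grid, value = as.numeric(value)),
            class = "concentration_trace")
}

# trapezoid integral of a sampled curve
curve_integral <- function(e) sum(trapz_weights(e$grid) * e$density)

#' Transform a concentration trace to a residence-time density
#'
#' Divides the (optionally baseline-corrected) concentration by its trapezoid
#' integral over the measurement window so the result integrates to one.
#'
#' @param trace A [concentration_trace()].
#' @param baseline Constant concentration to subtract before normalizing
#'   (e.g. 100 for an impulse riding on an on-target stream). Default 0.
#' @param baseline_window If positive, the mean of the first
#'   `baseline_window` seconds is used as the baseline instead; default
#'   `NULL` (off).
#' @return An [et_curve()]; noisy inputs may yield locally negative density.
#' @export
normalize_to_E <- function(trace, baseline = 0, baseline_window = NULL) {
  stopifnot(inherits(trace, "concentration_trace"))
  if (trace$grid$n_points < 2L)
    stop("normalize_to_E: trace must have at least 2 points", call. = FALSE)
  v <- trace$value
  if (!is.null(baseline_window) && baseline_window > 0) {
    tt <- grid_times(trace$grid)
    pre <- v[tt <= tt[1L] + baseline_window]
    baseline <- mean(pre)
  }
  v <- v - baseline
  int <- sum(trapz_weights(trace$grid) * v)
  if (!is.finite(int) || int <= 0)
    stop("normalize_to_E: trace integrates to a non-positive value; ",
         "cannot form a probability density", call. = FALSE)
  et_curve(trace$grid, v / int, normalized = TRUE, tol = 1e-9,
           allow_negative = TRUE)
}

#' Mean residence time of a density
#'
#' First moment of E(t) by trapezoid quadrature: the average time material
#' spends in the unit.
#'
#' @param e An [et_curve()] integrating to 1 within `tol`.
#' @param tol Allowed deviation of the curve integral from 1.
#' @return Mean residence time in seconds.
#' @export
mrt_of_curve <- function(e, tol = 1e-3) {
  stopifnot(inherits(e, "et_curve"))
  int <- curve_integral(e)
  if (abs(int - 1) > tol)
    stop(sprintf("mrt_of_curve: curve integrates to %.6g; normalize first",
                 int), call. = FALSE)
  sum(trapz_weights(e$grid) * grid_times(e$grid) * e$density)
}

# renormalize a density on its grid (absorbs truncation loss)
renormalize <- function(e) {
  int <- curve_integral(e)
  if (int <= 0) stop("cannot renormalize a curve with non-positive mass",
                     call. = FALSE)
  et_curve(e$grid, e$density / int, normalized = TRUE, tol = 1e-9,
           allow_negative = any(e$density < 0))
}

#' Cumulative distribution of a residence-time density
#'
#' @param e An [et_curve()].
#' @return Numeric vector F(t) at the grid nodes (cumulative trapezoid).
#' @export
curve_cdf <- function(e) {
  stopifnot(inherits(e, "et_curve"))
  d <- e$density
  h <- e$grid$step
  c(0, cumsum((d[-length(d)] + d[-1L]) / 2 * h))
}

#' @export
print.et_curve <- function(x, ...) {
  cat(sprintf("<et_curve> %d points, step %g s, integral %.6f, MRT %.4g s\n",
              x$grid$n_points, x$grid$step, curve_integral(x),
              tryCatch(mrt_of_curve(x), error = function(e) NA_real_)))
  invisible(x)
}

#' @export
print.concentration_trace <- function(x, ...) {
  cat(sprintf("<concentration_trace> %d points, step %g s, range [%.3g, %.3g] %%LC\n",
              x$grid$n_points, x$grid$step, min(x$value), max(x$value)))
  invisible(x)
}

#' @export
plot.et_curve <- function(x, ...) {
  graphics::plot(grid_times(x$grid), x$density, type = "l",
                 xlab = "time (s)", ylab = "E(t) (1/s)", ...)
  invisible(x)
}

#' @export
plot.concentration_trace <- function(x, ...) {
  graphics::plot(grid_times(x$grid), x$value, type = "l",
                 xlab = "time (s)", ylab = "concentration (%LC)", ...)
  invisible(x)
}
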