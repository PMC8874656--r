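#' Uniform time grid
#'
#' Constructs the uniform time axis on which residence-time densities and
#' concentration traces are sampled. All grids in the package are uniform;
#' irregular time stamps are rejected at the I/O layer rather than resampled.
#'
#' @param start First time point in seconds (default 0).
#' @param step Grid spacing in seconds; must be positive.
#' @param n_points Number of grid nodes; at least 2.
#' @return An object of class `time_grid`.
#' @examples
#' g <- time_grid(step = 1, n_points = 600)
#' head(grid_times(g))
#' @export
time_grid <- function(start = 0, step = 1, n_points) {
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("time_grid: `step` must be a single positive number", call. = FALSE)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L)
    stop("time_grid: `n_points` must be an integer >= 2", call. = FALSE)
  if (!is.finite(start)) stop("time_grid: `start` must be finite", call. = FALSE)
  structure(list(start = start, step = step, n_points = n_points),
            class = "time_grid")
}

#' @rdname time_grid
#' @param grid A `time_grid`.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$start + grid$step * (seq_len(grid$n_points) - 1L)
}

#' @rdname time_grid
#' @export
grid_end <- function(grid) grid$start + grid$step * (grid$n_points - 1L)

#' Build a time grid from a vector of (supposedly uniform) time stamps
#'
#' @param times Numeric vector of strictly increasing, uniformly spaced times.
#' @param tol Relative tolerance on spacing uniformity.
#' @return A `time_grid`.
#' @keywords internal
#' @export
grid_from_times <- function(times, tol = 1e-6) {
  if (length(times) < 2L) stop("need at least 2 time points", call. = FALSE)
  d <- diff(times)
  if (any(d <= 0)) stop("time stamps must be strictly increasing", call. = FALSE)
  step <- stats::median(d)
  if (any(abs(d - step) > tol * max(step, 1)))
    stop("time stamps are not uniformly spaced; resampling is not performed",
         call. = FALSE)
  time_grid(start = times[1L], step = step, n_points = length(times))
}

same_grid <- function(g1, g2, tol = 1e-9) {
  abs(g1$start - g2$start) <= tol &&
    abs(g1$step - g2$step) <= tol * max(g1$step, 1) &&
    g1$n_points == g2$n_points
}

# trapezoid quadrature weights on a uniform grid
trapz_weights <- function(grid) {
  w <- rep(grid$step, grid$n_points)
  w[c(1L, grid$n_points)] <- grid$step / 2
  w
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> start=%g s, step=%g s, n=%d (end=%g s)\n",
              x$start, x$step, x$n_points, grid_end(x)))
  invisible(x)
}
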