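#' Empirical mean-residence-time surface constants
#'
#' The MRT of each blender is modeled empirically over the operating
#' region as
#' \deqn{MRT = A/\dot m + B/\beta + C/(\dot m \beta) + D}
#' with mass flow \eqn{\dot m} (kg/h) and impeller speed \eqn{\beta}
#' (rpm); the feed frame, whose paddle speed is tied to the flow, uses
#' \deqn{MRT = E/\dot m^2 + D.}
#' Every term is inverse in the operating variables, reflecting the
#' observed shortening of residence time as throughput and agitation
#' increase.
#'
#' @param unit `"blender1"`, `"blender2"` or `"feedframe"`.
#' @param A,B,C,D,E Surface constants. Blender records carry A, B, C, D
#'   (units s.kg/h, s.rpm, s.kg.rpm/h, s); feed-frame records carry E, D
#'   (s.kg^2/h^2, s).
#' @return An object of class `empirical_constants`.
#' @export
empirical_constants <- function(unit, A = NULL, B = NULL, C = NULL,
                                D, E = NULL) {
  unit <- match.arg(unit, c("blender1", "blender2", "feedframe"))
  if (unit == "feedframe") {
    if (is.null(E)) stop("feed-frame constants require E", call. = FALSE)
    if (!is.null(A) || !is.null(B) || !is.null(C))
      stop("feed-frame constants carry only E and D", call. = FALSE)
  } else {
    if (is.null(A) || is.null(B) || is.null(C))
      stop("blender constants require A, B, C and D", call. = FALSE)
    if (!is.null(E))
      stop("blender constants carry no E term", call. = FALSE)
  }
  structure(list(unit = unit, A = A, B = B, C = C, D = D, E = E),
            class = "empirical_constants")
}

#' @export
print.empirical_constants <- function(x, ...) {
  if (x$unit == "feedframe")
    cat(sprintf("<empirical_constants> %s: E=%.4g, D=%.4g\n", x$unit, x$E, x$D))
  else
    cat(sprintf("<empirical_constants> %s: A=%.4g, B=%.4g, C=%.4g, D=%.4g\n",
                x$unit, x$A, x$B, x$C, x$D))
  invisible(x)
}

#' Evaluate an empirical MRT surface at an operating condition
#'
#' @param constants An [empirical_constants()].
#' @param condition An [operating_condition()]; blender surfaces require
#'   the matching impeller speed.
#' @return Predicted mean residence time in seconds.
#' @examples
#' ff <- reference_constants()$feedframe
#' predict_mrt(ff, operating_condition(90))   # ~68.5 s
#' @export
predict_mrt <- function(constants, condition) {
  stopifnot(inherits(constants, "empirical_constants"),
            inherits(condition, "operating_condition"))
  m <- condition$mass_flow
  if (constants$unit == "feedframe")
    return(constants$E / m^2 + constants$D)
  beta <- condition_speed(condition, constants$unit)
  if (is.null(beta))
    stop(sprintf("predict_mrt: condition lacks the %s impeller speed",
                 constants$unit), call. = FALSE)
  constants$A / m + constants$B / beta + constants$C / (m * beta) + constants$D
}

#' Fit an empirical MRT surface by weighted linear least squares
#'
#' The surfaces are linear in their constants, so the weighted
#' least-squares problem is solved in closed form (via `stats::lm`).
#' Each observation's residual is weighted by the inverse of its fit
#' statistic `eps`, i.e. weight `1/eps^2` on the squared residual, so
#' poorly determined MRT values influence the surface less.
#'
#' @param observations A data frame with columns `mass_flow`, `mrt`,
#'   `eps`, and `speed` for the blender form.
#' @param form `"blender"` or `"feedframe"`.
#' @param unit Unit label stored in the result (defaults to the form).
#' @return An [empirical_constants()].
#' @export
fit_empirical <- function(observations, form = c("blender", "feedframe"),
                          unit = NULL) {
  form <- match.arg(form)
  obs <- as.data.frame(observations)
  need <- c("mass_flow", "mrt", if (form == "blender") "speed")
  if (!all(need %in% names(obs)))
    stop("fit_empirical: observations need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!"eps" %in% names(obs) || any(!is.finite(obs$eps)) || any(obs$eps <= 0))
    obs$eps <- rep(1, nrow(obs))
  n_min <- if (form == "blender") 4L else 2L
  if (nrow(obs) < n_min)
    stop(sprintf("fit_empirical: %s form needs at least %d observations",
                 form, n_min), call. = FALSE)
  if (form == "blender") {
    X <- cbind(A = 1 / obs$mass_flow, B = 1 / obs$speed,
               C = 1 / (obs$mass_flow * obs$speed), D = 1)
  } else {
    X <- cbind(E = 1 / obs$mass_flow^2, D = 1)
  }
  if (qr(X)$rank < ncol(X))
    stop("fit_empirical: design is rank-deficient; vary the operating ",
         "conditions (e.g. more than one mass flow)", call. = FALSE)
  fit <- stats::lm.wfit(X, obs$mrt, w = 1 / obs$eps^2)
  cf <- fit$coefficients
  if (form == "blender") {
    if (is.null(unit)) unit <- "blender1"
    empirical_constants(unit, A = cf[["A"]], B = cf[["B"]], C = cf[["C"]],
                        D = cf[["D"]])
  } else {
    empirical_constants("feedframe", D = cf[["D"]], E = cf[["E"]])
  }
}

#' Unit RTD parameters at an operating condition from an empirical surface
#'
#' Evaluates the surface MRT at the condition and inverts it with the
#' unit's shared ratio constant to (tau_tank, theta).
#'
#' @param condition An [operating_condition()].
#' @param constants An [empirical_constants()].
#' @param shared_r The unit's ratio constant `R` (> 0).
#' @return An [rtd_params()].
#' @export
rtd_params_at <- function(condition, constants, shared_r) {
  mrt <- predict_mrt(constants, condition)
  if (!is.finite(mrt) || mrt <= 0)
    stop(sprintf(
      "rtd_params_at: predicted MRT %.3g s at %g kg/h is non-positive; the condition lies outside the usable region",
      mrt, condition$mass_flow), call. = FALSE)
  params_from_mrt_r(mrt, shared_r)
}

#' Parity statistics between observed and predicted values
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2).
#' @return A list with `r_squared` (squared Pearson correlation) and
#'   `rmse` (root mean squared difference).
#' @export
parity_stats <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stop("parity_stats: need equal-length vectors with n >= 2", call. = FALSE)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("parity_stats: zero variance; correlation undefined", call. = FALSE)
  list(r_squared = stats::cor(observed, predicted)^2,
       rmse = sqrt(mean((observed - predicted)^2)))
}
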