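#' Tracer impulse experiment record
#'
#' One recorded impulse response: a known tracer mass injected at a unit
#' inlet and the outlet concentration trace. `target_unit` names the most
#' upstream unit the response traverses: `"blender2"` (NIR at the Blender 2
#' outlet, Blender 2 pulse), `"blender1"` (NIR trace of a Blender 1 pulse,
#' which carries both blenders' mixing), or `"full_system"` (tablet assay
#' of a Blender 1 pulse, carrying all three units).
#'
#' @param target_unit `"blender1"`, `"blender2"` or `"full_system"`.
#' @param condition An [operating_condition()].
#' @param tracer_mass Injected tracer mass in grams (> 0).
#' @param trace A [concentration_trace()] covering the full response.
#' @param replicate_id Replicate label (default "r1").
#' @return An object of class `impulse_experiment`.
#' @export
impulse_experiment <- function(target_unit, condition, tracer_mass, trace,
                               replicate_id = "r1") {
  target_unit <- match.arg(target_unit,
                           c("blender1", "blender2", "full_system"))
  stopifnot(inherits(condition, "operating_condition"),
            inherits(trace, "concentration_trace"))
  if (!is.finite(tracer_mass) || tracer_mass <= 0)
    stop("impulse_experiment: tracer_mass must be > 0", call. = FALSE)
  structure(list(target_unit = target_unit, condition = condition,
                 tracer_mass = tracer_mass, trace = trace,
                 replicate_id = as.character(replicate_id)),
            class = "impulse_experiment")
}

#' Fitting control settings
#'
#' @param step Internal model-grid step in seconds (default 1, the NIR
#'   cadence; model curves are interpolated to the data time stamps).
#' @param n_starts Number of multi-start initial guesses (Latin hypercube
#'   around the moment-based start); the joint problem is non-linear and
#'   benefits from restarts.
#' @param seed RNG seed for the multi-start draw.
#' @param tau_bounds,r_bounds Box bounds on tau (s) and the ratio constant.
#' @param baseline Constant baseline subtracted from traces before
#'   normalization (see [normalize_to_E()]).
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(step = 1, n_starts = 8, seed = 1234,
                        tau_bounds = c(0.1, 1e4), r_bounds = c(1e-3, 1e6),
                        baseline = 0, maxiter = 200) {
  stopifnot(step > 0, n_starts >= 1, tau_bounds[1] > 0, r_bounds[1] > 0)
  structure(list(step = step, n_starts = as.integer(n_starts), seed = seed,
                 tau_bounds = tau_bounds, r_bounds = r_bounds,
                 baseline = baseline, maxiter = maxiter),
            class = "fit_control")
}

# evaluate a function with a private RNG stream, restoring caller state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# the unit whose parameters a set of experiments determines
target_to_fit_unit <- function(target_unit) {
  switch(target_unit, blender2 = "blender2", blender1 = "blender1",
         full_system = "feedframe")
}

condition_key <- function(condition, fit_unit) {
  sp <- condition_speed(condition, fit_unit)
  if (is.null(sp)) sprintf("%g", condition$mass_flow)
  else sprintf("%g@%g", condition$mass_flow, sp)
}

#' Look up fitted parameters at an operating condition
#'
#' @param result A [fit_unit_joint()] result.
#' @param condition An [operating_condition()].
#' @return An [rtd_params()].
#' @export
params_at_condition <- function(result, condition) {
  stopifnot(inherits(result, "unit_fit_result"))
  pc <- result$per_condition
  sp <- condition_speed(condition, result$unit)
  hit <- abs(pc$mass_flow - condition$mass_flow) < 1e-9
  if (!is.null(sp)) hit <- hit & !is.na(pc$speed) & abs(pc$speed - sp) < 1e-9
  i <- which(hit)
  if (length(i) != 1L)
    stop(sprintf(
      "no fitted %s parameters at %g kg/h%s; upstream characterization missing for this condition",
      result$unit, condition$mass_flow,
      if (!is.null(sp)) sprintf(" / %g rpm", sp) else ""), call. = FALSE)
  rtd_params(tau_tank = pc$tau_tank[i], theta = pc$theta[i],
             eps_tau = pc$eps_tau[i], eps_r = result$eps_r)
}

# known-upstream kernel (convolution of already-characterized units) for one
# experiment, on the model grid; NULL if the experiment sees no known unit
upstream_kernel <- function(experiment, known_upstream, grid) {
  need <- switch(experiment$target_unit,
                 blender2 = character(0),
                 blender1 = "blender2",
                 full_system = c("blender1", "blender2"))
  if (length(need) == 0L) return(NULL)
  kern <- NULL
  for (u in need) {
    res <- Filter(function(r) identical(r$unit, u), known_upstream)
    if (length(res) == 0L)
      stop(sprintf("fit_unit_joint: %s parameters are required upstream of a %s experiment but were not supplied",
                   u, experiment$target_unit), call. = FALSE)
    p <- params_at_condition(res[[1L]], experiment$condition)
    ek <- suppressWarnings(e_unit(p, grid))
    kern <- if (is.null(kern)) ek else convolve_rtd(kern, ek)
  }
  kern
}

#' Joint constrained regression of unit RTD parameters
#'
#' Fits the delay + two-equal-tank model to normalized impulse densities
#' from one target unit at several operating conditions simultaneously:
#' one tank time `tau_i` per condition plus a single ratio constant
#' `R = tau/theta` shared by all conditions of the unit. For Blender 1
#' and full-system (tablet) data the candidate kernel is convolved with
#' the already-characterized downstream kernels before comparison
#' (forward deconvolution), never divided.
#'
#' Least squares on the density scale is solved by Levenberg-Marquardt
#' with log-parameterization and multi-starts; per-parameter fit
#' statistics are asymptotic standard errors from the Jacobian at the
#' optimum, propagated to the MRT via [epsilon_mrt()].
#'
#' @param experiments List of [impulse_experiment()] for one target unit.
#' @param known_upstream List of previous `unit_fit_result`s supplying
#'   downstream-unit parameters where the response traverses them.
#' @param control A [fit_control()].
#' @return An object of class `unit_fit_result` with elements `unit`,
#'   `per_condition` (data frame: mass_flow, speed, tau_tank, theta, mrt,
#'   eps_tau, eps_mrt), `shared_r`, `eps_r`, `n_parameters`,
#'   `residual_sse`. `n_parameters` follows the reporting convention that
#'   counts each tank time, the shared ratio constant, and each
#'   per-condition fit statistic (2 x conditions + 1); the optimizer's
#'   free unknowns number conditions + 1.
#' @export
fit_unit_joint <- function(experiments, known_upstream = list(),
                           control = fit_control()) {
  if (length(experiments) == 0L)
    stop("fit_unit_joint: no experiments supplied", call. = FALSE)
  stopifnot(all(vapply(experiments, inherits, TRUE, "impulse_experiment")))
  tgt <- unique(vapply(experiments, function(e) e$target_unit, ""))
  if (length(tgt) != 1L)
    stop("fit_unit_joint: experiments mix target units", call. = FALSE)
  fit_unit <- target_to_fit_unit(tgt)

  keys <- vapply(experiments, function(e) condition_key(e$condition, fit_unit), "")
  ukeys <- unique(keys)
  K <- length(ukeys)

  # per-condition data blocks: normalized density at its time stamps,
  # model grid spanning the data, fixed upstream kernel
  blocks <- lapply(ukeys, function(k) {
    exps <- experiments[keys == k]
    cond <- exps[[1L]]$condition
    tmax <- max(vapply(exps, function(e) grid_end(e$trace$grid), 0))
    mgrid <- time_grid(0, control$step,
                       n_points = max(3L, ceiling(tmax / control$step) + 1L))
    up <- upstream_kernel(exps[[1L]], known_upstream, mgrid)
    dat <- lapply(exps, function(e) {
      E <- normalize_to_E(e$trace, baseline = control$baseline)
      list(t = grid_times(E$grid), y = E$density)
    })
    emp_mrt <- mean(vapply(exps, function(e) {
      mrt_of_curve(normalize_to_E(e$trace, baseline = control$baseline))
    }, 0))
    up_mrt <- if (is.null(up)) 0 else mrt_of_curve(up)
    list(key = k, condition = cond, grid = mgrid, upstream = up,
         data = dat, emp_mrt = emp_mrt, up_mrt = up_mrt)
  })

  tb <- log(control$tau_bounds); rb <- log(control$r_bounds)
  clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])

  residual_fn <- function(p) {
    ltau <- p[seq_len(K)]; lr <- p[K + 1L]
    tau <- exp(ltau); r <- exp(lr)
    out <- vector("list", K)
    for (i in seq_len(K)) {
      b <- blocks[[i]]
      theta <- tau[i] / r
      if (theta + tau[i] > grid_end(b$grid)) {
        # candidate kernel pushed past the observation window: penalize
        out[[i]] <- rep(1, sum(lengths(lapply(b$data, `[[`, "t"))))
        next
      }
      ek <- suppressWarnings(e_unit(list(tau_tank = tau[i], theta = theta),
                                    b$grid))
      if (!is.null(b$upstream)) ek <- convolve_rtd(ek, b$upstream)
      mt <- grid_times(b$grid)
      out[[i]] <- unlist(lapply(b$data, function(d) {
        stats::approx(mt, ek$density, xout = d$t, rule = 2)$y - d$y
      }))
    }
    unlist(out)
  }

  # moment-based start: tau0 = half the data MRT net of the upstream MRT
  tau0 <- vapply(blocks, function(b) max(pmax(b$emp_mrt - b$up_mrt, 2) / 2,
                                         control$tau_bounds[1] * 2), 0)
  p0 <- c(clamp(log(tau0), tb), clamp(log(1), rb))

  starts <- list(p0)
  if (control$n_starts > 1L) {
    U <- with_seed(control$seed,
                   lhs::randomLHS(control$n_starts - 1L, K + 1L))
    for (s in seq_len(nrow(U))) {
      lt <- clamp(log(tau0) + (U[s, seq_len(K)] - 0.5) * 2 * log(4), tb)
      lrs <- clamp(log(1e-2) + U[s, K + 1L] * (log(1e3) - log(1e-2)), rb)
      starts[[s + 1L]] <- c(lt, lrs)
    }
  }

  lower <- c(rep(tb[1], K), rb[1]); upper <- c(rep(tb[2], K), rb[2])
  sse0 <- sum(residual_fn(p0)^2)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = residual_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = control$maxiter)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("fit_unit_joint: optimizer failed to converge from any of the ",
         length(starts), " starts; inspect the input curves", call. = FALSE)
  if (best$deviance > sse0 + 1e-12)
    best$par <- p0  # never worse than the moment start

  p_hat <- best$par
  tau_hat <- exp(p_hat[seq_len(K)]); r_hat <- exp(p_hat[K + 1L])
  res_hat <- residual_fn(p_hat)
  sse <- sum(res_hat^2)
  N <- length(res_hat); P <- K + 1L

  # numeric central-difference Jacobian in log space -> asymptotic SEs
  J <- matrix(0, N, P)
  hstep <- 1e-5
  for (j in seq_len(P)) {
    pp <- p_hat; pm <- p_hat
    pp[j] <- pp[j] + hstep; pm[j] <- pm[j] - hstep
    J[, j] <- (residual_fn(pp) - residual_fn(pm)) / (2 * hstep)
  }
  sigma2 <- if (N > P) sse / (N - P) else 0
  JtJ <- crossprod(J)
  covm <- tryCatch(solve(JtJ), error = function(e) MASS::ginv(JtJ))
  se_log <- sqrt(pmax(diag(covm), 0) * sigma2)
  eps_tau <- tau_hat * se_log[seq_len(K)]       # delta method from log scale
  eps_r <- r_hat * se_log[K + 1L]

  conds <- lapply(blocks, `[[`, "condition")
  per <- data.frame(
    mass_flow = vapply(conds, function(c) c$mass_flow, 0),
    speed = vapply(conds, function(c) {
      s <- condition_speed(c, fit_unit); if (is.null(s)) NA_real_ else s
    }, 0),
    tau_tank = tau_hat,
    theta = tau_hat / r_hat,
    mrt = mrt_from_tau_r(tau_hat, r_hat),
    eps_tau = eps_tau,
    eps_mrt = epsilon_mrt(tau_hat, r_hat, eps_tau, eps_r))
  per <- per[order(per$mass_flow, per$speed), , drop = FALSE]
  rownames(per) <- NULL

  structure(list(unit = fit_unit, per_condition = per, shared_r = r_hat,
                 eps_r = eps_r, n_parameters = 2L * K + 1L,
                 residual_sse = sse, n_conditions = K,
                 n_residuals = N),
            class = "unit_fit_result")
}

#' @export
print.unit_fit_result <- function(x, ...) {
  cat(sprintf("<unit_fit_result> %s: %d conditions, shared R = %.4g (eps %.2g), SSE = %.4g\n",
              x$unit, x$n_conditions, x$shared_r, x$eps_r, x$residual_sse))
  print(x$per_condition, digits = 4)
  invisible(x)
}

#' Sequential deconvolution of the full impulse campaign
#'
#' Runs [fit_unit_joint()] in the only feasible order for an in-series
#' line: Blender 2 first (its pulses are measured directly), then
#' Blender 1 (its pulses carry both blenders; the Blender 2 kernel is
#' supplied as known), then the feed frame (tablet data carry all three
#' units; both blender kernels supplied).
#'
#' @param all_experiments List of [impulse_experiment()] covering all
#'   three target levels.
#' @param control A [fit_control()].
#' @return A list with `unit_fit_result`s `blender2`, `blender1`,
#'   `feedframe`.
#' @export
deconvolution_sequence <- function(all_experiments, control = fit_control()) {
  tgt <- vapply(all_experiments, function(e) e$target_unit, "")
  split_exps <- split(all_experiments, tgt)
  for (need in c("blender2", "blender1", "full_system"))
    if (is.null(split_exps[[need]]))
      stop(sprintf("deconvolution_sequence: no %s experiments supplied; the sequence cannot proceed",
                   need), call. = FALSE)
  b2 <- fit_unit_joint(split_exps$blender2, control = control)
  b1 <- fit_unit_joint(split_exps$blender1, known_upstream = list(b2),
                       control = control)
  ff <- fit_unit_joint(split_exps$full_system,
                       known_upstream = list(b1, b2), control = control)
  list(blender2 = b2, blender1 = b1, feedframe = ff)
}

#' Per-condition MRT and propagated fit statistic of a fitted unit
#'
#' @param result A [fit_unit_joint()] result.
#' @return A data frame (mass_flow, speed, mrt, eps_mrt) sorted by mass
#'   flow then speed.
#' @export
goodness_of_fit <- function(result) {
  stopifnot(inherits(result, "unit_fit_result"))
  out <- result$per_condition[, c("mass_flow", "speed", "mrt", "eps_mrt")]
  out <- out[order(out$mass_flow, out$speed), , drop = FALSE]
  rownames(out) <- NULL
  out
}
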