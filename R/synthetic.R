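#' Measurement noise model
#'
#' Additive Gaussian noise on the %LC scale. The NIR blend monitor's
#' default sigma of 2.6 %LC matches the cross-validation error of a
#' typical PLS blend calibration; the tablet HPLC assay is tighter
#' (default 1.0 %LC).
#'
#' @param nir_sigma NIR noise standard deviation, %LC (>= 0).
#' @param hplc_sigma HPLC noise standard deviation, %LC (>= 0).
#' @param seed Optional integer seed. When set, each generator call
#'   produces identical output across runs; when `NA` the generators
#'   draw from the ambient RNG stream (used when a campaign-level seed
#'   already governs the stream).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(nir_sigma = 2.6, hplc_sigma = 1.0, seed = NA) {
  if (nir_sigma < 0 || hplc_sigma < 0)
    stop("noise_model: sigmas must be >= 0", call. = FALSE)
  structure(list(nir_sigma = nir_sigma, hplc_sigma = hplc_sigma,
                 seed = seed), class = "noise_model")
}

maybe_seeded <- function(noise, expr) {
  if (!is.null(noise$seed) && !is.na(noise$seed))
    with_seed(noise$seed, expr)
  else force(expr)
}

# grams per second of total mass flow given kg/h
flow_gs <- function(mass_flow) mass_flow * 1000 / 3600

#' Tracer mass recovered from a simulated impulse trace
#'
#' Integrates the baseline-subtracted concentration times the API mass
#' flow: for a conservative tracer this returns the injected mass.
#'
#' @param trace A [concentration_trace()].
#' @param mass_flow Total line mass flow, kg/h.
#' @param api_fraction API mass fraction of the formulation (default
#'   0.25).
#' @param baseline Baseline concentration in %LC subtracted before
#'   integration.
#' @return Recovered tracer mass in grams.
#' @export
tracer_mass_recovered <- function(trace, mass_flow, api_fraction = 0.25,
                                  baseline = 0) {
  v <- (trace$value - baseline) / 100 * api_fraction * flow_gs(mass_flow)
  sum(trapz_weights(trace$grid) * v)
}

#' Simulate a tracer impulse experiment
#'
#' Passes a delta of `tracer_mass` grams of API through the kernel the
#' pulse traverses (Blender 2 alone for a Blender 2 pulse; Blender 1
#' convolved with Blender 2 for a Blender 1 pulse, since the NIR sits at
#' the Blender 2 outlet; all three units for the tablet response),
#' converts to %LC, samples at the measurement cadence, and adds
#' Gaussian noise (NIR sigma for blend traces, HPLC sigma for tablets).
#'
#' @param target_unit `"blender1"`, `"blender2"` or `"full_system"`.
#' @param condition An [operating_condition()].
#' @param truth Named list of [rtd_params()] (`blender1`, `blender2`,
#'   `feedframe`) covering the target unit and everything downstream of
#'   the pulse.
#' @param tracer_mass Grams of tracer (defaults: 30 g for Blender 2
#'   pulses, 100 g otherwise).
#' @param noise A [noise_model()].
#' @param api_fraction API mass fraction of the formulation.
#' @param baseline Baseline concentration (%LC) the pulse rides on.
#' @param cadence Sampling cadence in seconds (default 1 for NIR traces,
#'   25 for tablet responses).
#' @param composite_n Tablets per composite HPLC assay (default 10);
#'   tablet responses carry the mean noise of `composite_n` tablets.
#' @return An [impulse_experiment()].
#' @export
gen_impulse <- function(target_unit, condition, truth,
                        tracer_mass = NULL, noise = noise_model(),
                        api_fraction = 0.25, baseline = 0,
                        cadence = NULL, composite_n = 10) {
  target_unit <- match.arg(target_unit,
                           c("blender1", "blender2", "full_system"))
  need <- switch(target_unit,
                 blender2 = "blender2",
                 blender1 = c("blender1", "blender2"),
                 full_system = c("blender1", "blender2", "feedframe"))
  for (u in need)
    if (is.null(truth[[u]]))
      stop(sprintf("gen_impulse: truth parameters for %s are required for a %s pulse",
                   u, target_unit), call. = FALSE)
  if (is.null(tracer_mass))
    tracer_mass <- if (target_unit == "blender2") 30 else 100
  if (is.null(cadence))
    cadence <- if (target_unit == "full_system") 25 else 1

  ps <- truth[need]
  fine <- do.call(default_grid, c(unname(ps), list(step = 1)))
  kern <- NULL
  for (u in need) {
    ek <- suppressWarnings(e_unit(truth[[u]], fine))
    kern <- if (is.null(kern)) ek else convolve_rtd(kern, ek)
  }
  excess <- 100 * tracer_mass * kern$density /
    (api_fraction * flow_gs(condition$mass_flow))

  maybe_seeded(noise, {
    if (cadence > 1) {
      keep <- seq(1L, fine$n_points, by = as.integer(round(cadence)))
      tt <- grid_times(fine)[keep]
      g <- time_grid(tt[1L], cadence, length(tt))
      v <- excess[keep]
    } else {
      g <- fine
      v <- excess
    }
    if (target_unit == "full_system") {
      # composite HPLC assay: mean of composite_n tablets per sample
      eps <- stats::rnorm(length(v), 0, noise$hplc_sigma / sqrt(composite_n))
    } else {
      eps <- stats::rnorm(length(v), 0, noise$nir_sigma)
    }
    v <- baseline + v + eps
    impulse_experiment(target_unit, condition, tracer_mass,
                       concentration_trace(g, v))
  })
}

#' Impulse campaign design over the studied operating region
#'
#' The characterization design for the line: Blender 2 pulses at every
#' combination of 4 mass flows (15, 25, 50, 90 kg/h) and 3 Blender 2
#' speeds (150, 210, 300 rpm); Blender 1 pulses at the same flows with
#' 3 Blender 1 speeds (180, 315, 450 rpm) at the Blender 2 center-point
#' speed; and full-system (tablet) responses at the center-point speeds
#' of both blenders at each flow, which isolate the feed frame.
#'
#' @param flows Mass flows in kg/h.
#' @param speeds_b1,speeds_b2 Impeller speed levels in rpm.
#' @param replicates Replicates per condition (>= 1).
#' @return A data frame with columns `target_unit`, `mass_flow`,
#'   `speed_b1`, `speed_b2`, `replicate`.
#' @export
campaign_design <- function(flows = c(15, 25, 50, 90),
                            speeds_b1 = c(180, 315, 450),
                            speeds_b2 = c(150, 210, 300),
                            replicates = 1) {
  stopifnot(replicates >= 1)
  ctr_b1 <- speeds_b1[ceiling(length(speeds_b1) / 2)]
  ctr_b2 <- speeds_b2[ceiling(length(speeds_b2) / 2)]
  d <- rbind(
    expand.grid(target_unit = "blender2", mass_flow = flows,
                speed_b1 = ctr_b1, speed_b2 = speeds_b2,
                stringsAsFactors = FALSE),
    expand.grid(target_unit = "blender1", mass_flow = flows,
                speed_b1 = speeds_b1, speed_b2 = ctr_b2,
                stringsAsFactors = FALSE),
    expand.grid(target_unit = "full_system", mass_flow = flows,
                speed_b1 = ctr_b1, speed_b2 = ctr_b2,
                stringsAsFactors = FALSE))
  d <- d[rep(seq_len(nrow(d)), each = replicates), , drop = FALSE]
  d$replicate <- as.integer(
    stats::ave(seq_len(nrow(d)), d$target_unit, d$mass_flow, d$speed_b1,
               d$speed_b2, FUN = seq_along))
  rownames(d) <- NULL
  d
}

# ground-truth parameters for a design row, from the reference tables
truth_for_row <- function(row) {
  lookup <- function(unit, speed) {
    tab <- reference_truth(unit)
    hit <- abs(tab$mass_flow - row$mass_flow) < 1e-9
    if (!is.null(speed)) hit <- hit & abs(tab$speed - speed) < 1e-9
    i <- which(hit)
    if (length(i) != 1L)
      stop(sprintf("no reference truth for %s at %g kg/h", unit,
                   row$mass_flow), call. = FALSE)
    rtd_params(tab$tau_tank[i], tab$theta[i])
  }
  list(blender1 = lookup("blender1", row$speed_b1),
       blender2 = lookup("blender2", row$speed_b2),
       feedframe = lookup("feedframe", NULL))
}

#' Simulate a full impulse campaign
#'
#' Generates one [impulse_experiment()] per design row, drawing the
#' unit ground truth from the reference characterization tables (or a
#' caller-supplied `truth_fn`). All noise flows from `seed`.
#'
#' @param design A [campaign_design()] data frame.
#' @param noise A [noise_model()] (its own `seed` field is ignored here).
#' @param seed Integer seed governing all noise in the campaign.
#' @param truth_fn Function(row) returning the named truth list for a
#'   design row; defaults to the reference tables.
#' @return A list of [impulse_experiment()].
#' @export
gen_campaign <- function(design = campaign_design(), noise = noise_model(),
                         seed = 1, truth_fn = truth_for_row) {
  noise$seed <- NA
  with_seed(seed, lapply(seq_len(nrow(design)), function(i) {
    row <- design[i, , drop = FALSE]
    cond <- operating_condition(row$mass_flow, speed_b1 = row$speed_b1,
                                speed_b2 = row$speed_b2)
    ex <- gen_impulse(row$target_unit, cond, truth_fn(row), noise = noise)
    ex$replicate_id <- sprintf("r%d", row$replicate)
    ex
  }))
}

#' Sample composite tablets from a predicted concentration trace
#'
#' Draws a composite sample every `cadence` seconds: `composite_n`
#' individual tablets each carry independent HPLC-scale noise and the
#' composite reports their mean, so composite noise shrinks by
#' `1/sqrt(composite_n)`.
#'
#' @param system_trace A [concentration_trace()] of tablet concentration.
#' @param cadence Sampling interval in seconds (within the trace span).
#' @param composite_n Tablets per composite (default 10).
#' @param noise A [noise_model()]; `hplc_sigma` is the per-tablet sigma.
#' @return A data frame with columns `time_s`, `value` (%LC).
#' @export
gen_tablet_samples <- function(system_trace, cadence, composite_n = 10,
                               noise = noise_model()) {
  stopifnot(inherits(system_trace, "concentration_trace"), cadence > 0)
  tt <- grid_times(system_trace$grid)
  if (cadence > tt[length(tt)] - tt[1L])
    stop("gen_tablet_samples: cadence exceeds the trace span", call. = FALSE)
  times <- seq(tt[1L] + cadence, tt[length(tt)], by = cadence)
  base <- stats::approx(tt, system_trace$value, xout = times)$y
  maybe_seeded(noise, {
    eps <- vapply(seq_along(times), function(i) {
      mean(stats::rnorm(composite_n, 0, noise$hplc_sigma))
    }, 0)
    data.frame(time_s = times, value = base + eps)
  })
}

#' Simulate a step-change validation dataset
#'
#' Runs a sequence of feeder concentration steps through the line kernel
#' at each mass flow and samples tablet assays at the t10, t50 and t90
#' of each step (the times at which 10/50/90% of the change has moved
#' through the system, from the kernel's cumulative distribution), in
#' duplicate composites. The default protocol — 3 flows, the step
#' sequence 100 -> 115 -> 100 -> 85 %LC (3 transitions per flow), 3 time
#' points, 2 duplicates — yields 54 measured/predicted pairs.
#'
#' @param flows Mass flows in kg/h.
#' @param kernels Named/indexed list of `system_kernel`s, one per flow;
#'   by default built from the reference truth at the center-point
#'   speeds.
#' @param steps Concentration levels in %LC, all within \[85, 115\].
#' @param duplicates Independent composite assays per time point.
#' @param noise A [noise_model()]; `hplc_sigma` is applied per composite.
#' @param seed Integer seed for the assay noise.
#' @return A data frame of class `validation_dataset` with columns
#'   `mass_flow`, `step`, `level_from`, `level_to`, `time_point`,
#'   `duplicate`, `time_s`, `measured`, `predicted`.
#' @export
gen_step_validation <- function(flows = c(15, 50, 90), kernels = NULL,
                                steps = c(100, 115, 100, 85),
                                duplicates = 2, noise = noise_model(),
                                seed = 1) {
  if (any(steps < 85 | steps > 115))
    stop("gen_step_validation: step levels must lie within [85, 115] %LC",
         call. = FALSE)
  if (length(steps) < 2L)
    stop("gen_step_validation: need at least one transition", call. = FALSE)
  if (is.null(kernels)) {
    kernels <- lapply(flows, function(f) {
      row <- list(mass_flow = f, speed_b1 = 315, speed_b2 = 210)
      tr <- truth_for_row(row)
      build_system_kernel(tr$blender1, tr$blender2, tr$feedframe)
    })
  }
  if (length(kernels) != length(flows))
    stop("gen_step_validation: need one kernel per flow", call. = FALSE)

  with_seed(seed, {
    out <- lapply(seq_along(flows), function(fi) {
      kern <- kernels[[fi]]
      k <- as_kernel_curve(kern)
      tt <- grid_times(k$grid); cdf <- curve_cdf(k)
      qf <- function(p) tt[which(cdf >= p)[1L]]
      t10 <- qf(0.10); t50 <- qf(0.50); t90 <- qf(0.90)
      hold <- ceiling(qf(0.999)) + k$grid$step
      step_t <- hold * seq_len(length(steps) - 1L)
      total <- hold * length(steps)
      g <- time_grid(0, k$grid$step, ceiling(total / k$grid$step) + 1L)
      gt <- grid_times(g)
      lev <- steps[findInterval(gt, c(-Inf, step_t))]
      feeder <- concentration_trace(g, lev)
      pred <- predict_downstream(feeder, kern, warmup = "keep")
      pv <- stats::approxfun(gt, pred$value)
      rows <- expand.grid(duplicate = seq_len(duplicates),
                          time_point = c("t10", "t50", "t90"),
                          step = seq_along(step_t),
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      off <- c(t10 = t10, t50 = t50, t90 = t90)
      rows$time_s <- step_t[rows$step] + off[rows$time_point]
      rows$predicted <- pv(rows$time_s)
      rows$measured <- rows$predicted +
        stats::rnorm(nrow(rows), 0, noise$hplc_sigma)
      rows$mass_flow <- flows[fi]
      rows$level_from <- steps[rows$step]
      rows$level_to <- steps[rows$step + 1L]
      rows
    })
    out <- do.call(rbind, out)
    out <- out[, c("mass_flow", "step", "level_from", "level_to",
                   "time_point", "duplicate", "time_s", "measured",
                   "predicted")]
    rownames(out) <- NULL
    class(out) <- c("validation_dataset", "data.frame")
    out
  })
}

#' Validation report against an RMSEP acceptance threshold
#'
#' @param dataset A [gen_step_validation()] dataset (or any data frame
#'   with `measured` and `predicted` columns).
#' @param threshold RMSEP acceptance criterion in %LC (default 6).
#' @return A list with `n_samples`, `rmsep`, `pass`, and the per-sample
#'   table.
#' @export
validation_report <- function(dataset, threshold = 6) {
  r <- rmsep(dataset$measured, dataset$predicted)
  list(n_samples = nrow(dataset), rmsep = r, pass = r <= threshold,
       threshold = threshold, samples = as.data.frame(dataset))
}
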