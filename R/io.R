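#' Read and write concentration traces as two-column CSV
#'
#' The on-disk format is a header line `time_s,value` followed by one
#' row per sample. Time stamps must be strictly increasing and uniform;
#' irregular stamps are rejected rather than resampled.
#'
#' @param path File path.
#' @return `read_trace()`: a [concentration_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("read_trace: no such file: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("read_trace: ", path, " must have columns time_s, value",
         call. = FALSE)
  bad <- which(!is.finite(df$time_s) | !is.finite(df$value))
  if (length(bad))
    stop(sprintf("read_trace: non-numeric or missing entry at line %d of %s",
                 bad[1L] + 1L, path), call. = FALSE)
  d <- diff(df$time_s)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L]
    stop(sprintf("read_trace: time stamps not strictly increasing at line %d of %s",
                 i + 2L, path), call. = FALSE)
  }
  concentration_trace(grid_from_times(df$time_s), df$value)
}

#' @rdname read_trace
#' @param trace A [concentration_trace()] or [et_curve()] (written with
#'   its density in the `value` column).
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "et_curve"))
    df <- data.frame(time_s = grid_times(trace$grid), value = trace$density)
  else if (inherits(trace, "concentration_trace"))
    df <- data.frame(time_s = grid_times(trace$grid), value = trace$value)
  else stop("write_trace: expected a concentration_trace or et_curve",
            call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize RTD parameters and fit results to JSON
#'
#' @param x An [rtd_params()], `unit_fit_result`, or list of
#'   [empirical_constants()].
#' @param path File path.
#' @export
write_params_json <- function(x, path) {
  strip <- function(o) {
    o <- unclass(o)
    o[!vapply(o, is.null, TRUE)]
  }
  payload <- if (inherits(x, "unit_fit_result")) {
    list(kind = "unit_fit_result", unit = x$unit, shared_r = x$shared_r,
         eps_r = x$eps_r, n_parameters = x$n_parameters,
         residual_sse = x$residual_sse, per_condition = x$per_condition)
  } else if (inherits(x, "rtd_params")) {
    c(list(kind = "rtd_params"), strip(x))
  } else if (is.list(x) && all(vapply(x, inherits, TRUE,
                                      "empirical_constants"))) {
    list(kind = "empirical_constants", units = lapply(x, strip))
  } else stop("write_params_json: unsupported object", call. = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(p$kind,
    rtd_params = rtd_params(p$tau_tank, p$theta, eps_tau = p$eps_tau %||% 0,
                            eps_r = p$eps_r %||% 0),
    unit_fit_result = structure(
      list(unit = p$unit, per_condition = as.data.frame(p$per_condition),
           shared_r = p$shared_r, eps_r = p$eps_r,
           n_parameters = p$n_parameters, residual_sse = p$residual_sse,
           n_conditions = nrow(as.data.frame(p$per_condition)),
           n_residuals = NA_integer_),
      class = "unit_fit_result"),
    empirical_constants = lapply(p$units, function(u) {
      do.call(empirical_constants,
              c(list(unit = u$unit),
                u[intersect(names(u), c("A", "B", "C", "D", "E"))]))
    }),
    stop("read_params_json: unknown payload kind: ", p$kind, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' Bundles every tunable of the synthetic end-to-end pipeline. Round
#' trips through JSON via [write_config()] / [read_config()].
#'
#' @param seed Master seed; all randomness flows from it.
#' @param step Model grid step, seconds.
#' @param n_starts Optimizer multi-starts.
#' @param nir_sigma,hplc_sigma Noise sigmas, %LC.
#' @param flows Campaign mass flows, kg/h.
#' @param replicates Impulse replicates per condition.
#' @param validation_flows Mass flows for the step-change validation.
#' @param rmsep_acceptance RMSEP acceptance criterion, %LC.
#' @param sigma_weight Tablet-weight variability, %LC.
#' @param out_dir Output directory for report files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, step = 1, n_starts = 8,
                       nir_sigma = 2.6, hplc_sigma = 1.0,
                       flows = c(15, 25, 50, 90), replicates = 1,
                       validation_flows = c(15, 50, 90),
                       rmsep_acceptance = 6, sigma_weight = 0,
                       out_dir = tempfile("rtdrun")) {
  stopifnot(step > 0, n_starts >= 1, replicates >= 1,
            rmsep_acceptance >= 0, sigma_weight >= 0)
  structure(list(seed = seed, step = step, n_starts = n_starts,
                 nir_sigma = nir_sigma, hplc_sigma = hplc_sigma,
                 flows = flows, replicates = replicates,
                 validation_flows = validation_flows,
                 rmsep_acceptance = rmsep_acceptance,
                 sigma_weight = sigma_weight, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, p)
}

#' Run the synthetic end-to-end pipeline
#'
#' Simulates an impulse campaign, fits all three units by sequential
#' deconvolution, fits the empirical MRT surfaces with inverse-eps
#' weighting, runs the synthetic step-change validation with the fitted
#' kernels, and computes the tightened rejection limits. Writes five
#' report files into `config$out_dir` (`unit_fits.json`,
#' `mrt_table.csv`, `empirical_constants.json`, `validation.csv`,
#' `limits.json`) plus `run.log`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `fits`, `constants`, `validation`,
#'   `limits`, `files`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat(sprintf("rtdcontrol pipeline, seed %d, %s\n", config$seed,
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")), file = logf)
  logline("package version %s", as.character(utils::packageVersion("rtdcontrol")))

  stage <- function(name, expr) {
    logline("stage %s ...", name)
    tryCatch(expr, error = function(e) {
      logline("stage %s FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  noise <- noise_model(config$nir_sigma, config$hplc_sigma)
  design <- campaign_design(flows = config$flows,
                            replicates = config$replicates)
  exps <- stage("simulate", gen_campaign(design, noise, seed = config$seed))
  ctrl <- fit_control(step = config$step, n_starts = config$n_starts,
                      seed = config$seed + 1000L)
  fits <- stage("deconvolution", deconvolution_sequence(exps, ctrl))

  constants <- stage("empirical-fit", {
    obs <- lapply(fits, goodness_of_fit)
    list(
      blender1 = fit_empirical(stats::setNames(obs$blender1,
                                               c("mass_flow", "speed", "mrt", "eps")),
                               "blender", unit = "blender1"),
      blender2 = fit_empirical(stats::setNames(obs$blender2,
                                               c("mass_flow", "speed", "mrt", "eps")),
                               "blender", unit = "blender2"),
      feedframe = fit_empirical(stats::setNames(obs$feedframe,
                                                c("mass_flow", "speed", "mrt", "eps")),
                                "feedframe"))
  })

  validation <- stage("validation", {
    kerns <- lapply(config$validation_flows, function(f) {
      cond_b1 <- operating_condition(f, speed_b1 = 315)
      cond_b2 <- operating_condition(f, speed_b2 = 210)
      build_system_kernel(params_at_condition(fits$blender1, cond_b1),
                          params_at_condition(fits$blender2, cond_b2),
                          params_at_condition(fits$feedframe,
                                              operating_condition(f)))
    })
    ds <- gen_step_validation(flows = config$validation_flows,
                              kernels = kerns, noise = noise,
                              seed = config$seed + 2000L)
    validation_report(ds, threshold = config$rmsep_acceptance)
  })

  limits <- stage("limits", rejection_limits(config$rmsep_acceptance,
                                             config$sigma_weight))

  files <- stage("reports", {
    f1 <- file.path(config$out_dir, "unit_fits.json")
    jsonlite::write_json(
      lapply(fits, function(x) list(
        unit = x$unit, shared_r = x$shared_r, eps_r = x$eps_r,
        n_parameters = x$n_parameters, residual_sse = x$residual_sse,
        per_condition = x$per_condition)),
      f1, auto_unbox = TRUE, digits = NA, dataframe = "columns")
    f2 <- file.path(config$out_dir, "mrt_table.csv")
    tab <- do.call(rbind, lapply(names(fits), function(u) {
      g <- goodness_of_fit(fits[[u]]); g$unit <- u; g
    }))
    utils::write.csv(tab, f2, row.names = FALSE)
    f3 <- file.path(config$out_dir, "empirical_constants.json")
    write_params_json(constants, f3)
    f4 <- file.path(config$out_dir, "validation.csv")
    utils::write.csv(validation$samples, f4, row.names = FALSE)
    f5 <- file.path(config$out_dir, "limits.json")
    jsonlite::write_json(unclass(limits), f5, auto_unbox = TRUE,
                         digits = NA)
    c(f1, f2, f3, f4, f5)
  })
  logline("validation RMSEP %.4f %%LC over %d samples (pass: %s)",
          validation$rmsep, validation$n_samples, validation$pass)
  logline("done")

  invisible(list(fits = fits, constants = constants,
                 validation = validation, limits = limits, files = files))
}
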