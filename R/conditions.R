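#' Operating condition of the line
#'
#' Total mass flow and, where relevant, blender impeller speeds. The
#' studied region is 15-90 kg/h, 180-450 rpm for Blender 1 and
#' 150-300 rpm for Blender 2; conditions outside it are rejected, since
#' neither the fitted RTD parameters nor the empirical surfaces are
#' meant to extrapolate.
#'
#' @param mass_flow Total line mass flow in kg/h, within \[15, 90\].
#' @param speed_b1 Blender 1 impeller speed in rpm, within \[180, 450\]
#'   (optional).
#' @param speed_b2 Blender 2 impeller speed in rpm, within \[150, 300\]
#'   (optional).
#' @return An object of class `operating_condition`.
#' @export
operating_condition <- function(mass_flow, speed_b1 = NULL, speed_b2 = NULL) {
  if (!is.finite(mass_flow) || mass_flow < 15 || mass_flow > 90)
    stop("operating_condition: mass_flow must lie in [15, 90] kg/h",
         call. = FALSE)
  if (!is.null(speed_b1) &&
      (!is.finite(speed_b1) || speed_b1 < 180 || speed_b1 > 450))
    stop("operating_condition: speed_b1 must lie in [180, 450] rpm",
         call. = FALSE)
  if (!is.null(speed_b2) &&
      (!is.finite(speed_b2) || speed_b2 < 150 || speed_b2 > 300))
    stop("operating_condition: speed_b2 must lie in [150, 300] rpm",
         call. = FALSE)
  structure(list(mass_flow = mass_flow, speed_b1 = speed_b1,
                 speed_b2 = speed_b2),
            class = "operating_condition")
}

#' @export
print.operating_condition <- function(x, ...) {
  cat(sprintf("<operating_condition> %g kg/h%s%s\n", x$mass_flow,
              if (!is.null(x$speed_b1)) sprintf(", B1 %g rpm", x$speed_b1) else "",
              if (!is.null(x$speed_b2)) sprintf(", B2 %g rpm", x$speed_b2) else ""))
  invisible(x)
}

# speed relevant for a unit's own surface / matching
condition_speed <- function(condition, unit) {
  switch(unit,
         blender1 = condition$speed_b1,
         blender2 = condition$speed_b2,
         feedframe = NULL,
         stop("unknown unit: ", unit, call. = FALSE))
}
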