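#' Published model coefficients
#'
#' All constants of the energy models in one place: the two log-linear
#' METs-vs-speed regression lines and their branch threshold, the quadratic
#' gradient-cost multiplier, the MET-to-VO2 and O2-to-energy conversions, the
#' ACSM walking/running equation coefficients with their 8 km/h threshold,
#' and the slope validity bound of the gradient-cost fit.
#'
#' The METs model is \eqn{\ln(\mathrm{METs}) = a v + b} with
#' \eqn{(a, b) = (0.224528, 0.254354)} below 8.69 km/h and
#' \eqn{(0.065439, 1.636715)} at or above it; the gradient cost is
#' \eqn{13.6524 \times 10^{-4} s^2 + 5.1921 \times 10^{-2} s + 1} for slope
#' \eqn{s} in percent, fitted on gradients up to ±45%. Defaults are the
#' published values; override individual constants only for sensitivity
#' analyses.
#'
#' @param ... named overrides of individual constants (must match existing
#'   names).
#'
#' @return An object of class `model_coefficients`: a named list with
#'   elements `eq1_slope`, `eq1_intercept`, `eq2_slope`, `eq2_intercept`,
#'   `speed_threshold_kmh`, `cost_a`, `cost_b`, `cost_c`,
#'   `met_vo2_ml_kg_min`, `kcal_per_l_o2`, `acsm_walk_speed_coef`,
#'   `acsm_walk_grade_coef`, `acsm_run_speed_coef`, `acsm_run_grade_coef`,
#'   `acsm_rest`, `acsm_threshold_kmh`, `slope_clip_pct`.
#'
#' @examples
#' coef <- model_coefficients()
#' coef$speed_threshold_kmh
#' model_coefficients(slope_clip_pct = 30)$slope_clip_pct
#' @export
model_coefficients <- function(...) {
  coef <- list(
    eq1_slope = 0.224528,       # per (km/h), speed < threshold
    eq1_intercept = 0.254354,   # ln METs
    eq2_slope = 0.065439,       # per (km/h), speed >= threshold
    eq2_intercept = 1.636715,   # ln METs
    speed_threshold_kmh = 8.69,
    cost_a = 13.6524e-4,        # per %^2
    cost_b = 5.1921e-2,         # per %
    cost_c = 1.0,               # Y-intercept: cost of flat travel
    met_vo2_ml_kg_min = 3.5,    # 1 MET in ml O2/kg/min
    kcal_per_l_o2 = 5.0,
    acsm_walk_speed_coef = 0.1, # ml/kg per m
    acsm_walk_grade_coef = 1.8,
    acsm_run_speed_coef = 0.2,
    acsm_run_grade_coef = 0.9,
    acsm_rest = 3.5,            # ml/kg/min
    acsm_threshold_kmh = 8.0,
    slope_clip_pct = 45.0       # gradient range of the source data
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(coef))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == ""))
      stop("unknown coefficient name(s): ", paste(bad, collapse = ", "))
    coef[names(overrides)] <- overrides
  }
  stopifnot(all(vapply(coef, function(x) is.numeric(x) && length(x) == 1L && x > 0, logical(1))))
  structure(coef, class = "model_coefficients")
}

#' @export
print.model_coefficients <- function(x, ...) {
  cat("Model coefficients (published defaults unless overridden)\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}
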