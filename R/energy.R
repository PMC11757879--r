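# Core energy models: piecewise log-linear METs from speed, quadratic
# gradient-cost multiplier, slope-adjusted METs, the ACSM reference
# equations, and accumulation of segment kinematics into totals.
#
# Unit conventions at every boundary (guarding against the classic 100x
# bug): the METs model takes slope in PERCENT; the ACSM equations take
# grade as a DECIMAL fraction (0.05 = 5%). Segments store percent; the
# accumulator converts where needed.

#' Horizontal METs from speed
#'
#' Piecewise log-linear model: \eqn{\exp(0.224528\,v + 0.254354)} below the
#' 8.69 km/h threshold and \eqn{\exp(0.065439\,v + 1.636715)} at or above
#' it. The two lines intersect at the threshold (branch disagreement about
#' 0.001 METs), so — unlike the ACSM walk/run pair — the model is
#' effectively continuous in speed.
#'
#' @param speed_kmh speed in km/h, >= 0 (vectorised). Speeds above 20 km/h
#'   warn: the fit extrapolates exponentially beyond the tabulated range of
#'   activity intensities it was built from.
#' @param coef a [model_coefficients()].
#' @return METs (multiples of resting metabolism).
#' @examples
#' mets_horizontal(c(0, 5, 10))
#' @export
mets_horizontal <- function(speed_kmh, coef = model_coefficients()) {
  check_speed(speed_kmh)
  if (any(speed_kmh > 20))
    warning("speed(s) above 20 km/h: METs model extrapolates beyond its source data")
  ifelse(speed_kmh < coef$speed_threshold_kmh,
         exp(coef$eq1_slope * speed_kmh + coef$eq1_intercept),
         exp(coef$eq2_slope * speed_kmh + coef$eq2_intercept))
}

#' Gradient cost multiplier
#'
#' Ratio of oxygen consumption on a gradient to horizontal travel at the
#' same speed: \eqn{13.6524\times10^{-4} s^2 + 5.1921\times10^{-2} s + 1}
#' for slope \eqn{s} in percent (rise/run x 100). The Y-intercept of 1
#' makes flat travel cost-neutral by construction. Slopes are clipped to
#' the fit's ±45% validity range, with a note counting clips.
#'
#' @param slope_pct slope in percent, signed (vectorised).
#' @param coef a [model_coefficients()].
#' @return Dimensionless cost multiplier, > 0 over the whole clipped range.
#' @examples
#' cost_of_slope(c(-10, 0, 10))
#' @export
cost_of_slope <- function(slope_pct, coef = model_coefficients()) {
  if (!is.numeric(slope_pct)) stop("`slope_pct` must be numeric")
  clip <- coef$slope_clip_pct
  n_clip <- sum(abs(slope_pct) > clip, na.rm = TRUE)
  if (n_clip) message("clipped ", n_clip, " slope(s) to +/-", clip, "%")
  s <- pmin(pmax(slope_pct, -clip), clip)
  coef$cost_a * s^2 + coef$cost_b * s + coef$cost_c
}

#' Slope-adjusted METs
#'
#' The model's central quantity: horizontal METs at the segment speed
#' multiplied by the gradient cost at the segment slope.
#'
#' @inheritParams mets_horizontal
#' @inheritParams cost_of_slope
#' @return METs on the gradient.
#' @examples
#' mets_on_slope(10, 10)
#' @export
mets_on_slope <- function(speed_kmh, slope_pct, coef = model_coefficients()) {
  mets_horizontal(speed_kmh, coef) * cost_of_slope(slope_pct, coef)
}

#' ACSM walking equation
#'
#' \eqn{VO_2 = 0.1\,v + 1.8\,v\,g + 3.5} ml/kg/min for speed \eqn{v} in
#' m/min and grade \eqn{g} as a decimal fraction; intended for speeds below
#' 8 km/h.
#'
#' @param speed_kmh speed in km/h, >= 0 (vectorised).
#' @param grade grade as a decimal fraction (0.05 = 5%), signed.
#' @param coef a [model_coefficients()].
#' @return VO2 rate in ml/kg/min.
#' @examples
#' acsm_walk_vo2(8, 0)   # 16.83: the walking side of the 8 km/h gap
#' @export
acsm_walk_vo2 <- function(speed_kmh, grade = 0, coef = model_coefficients()) {
  check_speed(speed_kmh)
  v_mpm <- speed_kmh * 1000 / 60
  v_mpm * coef$acsm_walk_speed_coef +
    v_mpm * grade * coef$acsm_walk_grade_coef + coef$acsm_rest
}

#' ACSM running equation
#'
#' \eqn{VO_2 = 0.2\,v + 0.9\,v\,g + 3.5} ml/kg/min for speed \eqn{v} in
#' m/min and grade \eqn{g} decimal; intended for speeds of 8 km/h and above.
#'
#' @inheritParams acsm_walk_vo2
#' @return VO2 rate in ml/kg/min.
#' @examples
#' acsm_run_vo2(8, 0)    # 30.17: the running side of the 8 km/h gap
#' @export
acsm_run_vo2 <- function(speed_kmh, grade = 0, coef = model_coefficients()) {
  check_speed(speed_kmh)
  v_mpm <- speed_kmh * 1000 / 60
  v_mpm * coef$acsm_run_speed_coef +
    v_mpm * grade * coef$acsm_run_grade_coef + coef$acsm_rest
}

#' Piecewise ACSM walk/run equation
#'
#' Walking equation below 8 km/h, running equation at or above — the
#' conventional speed-switched application of the two ACSM equations. Note
#' the ~13.3 ml/kg/min discontinuity at exactly 8 km/h on the flat, the
#' inconsistency that motivates the continuous METs model.
#'
#' @inheritParams acsm_walk_vo2
#' @return VO2 rate in ml/kg/min.
#' @export
acsm_rw_vo2 <- function(speed_kmh, grade = 0, coef = model_coefficients()) {
  check_speed(speed_kmh)
  # 1e-6 km/h guard: speeds reconstructed from coordinates land a few ULPs
  # off the threshold; a micro-km/h is far below GPS resolution.
  ifelse(speed_kmh < coef$acsm_threshold_kmh - 1e-6,
         acsm_walk_vo2(speed_kmh, grade, coef),
         acsm_run_vo2(speed_kmh, grade, coef))
}

check_speed <- function(speed_kmh) {
  if (!is.numeric(speed_kmh)) stop("speed must be numeric")
  if (any(speed_kmh < 0, na.rm = TRUE)) stop("speed must be >= 0")
  invisible(speed_kmh)
}

#' Per-segment energy table
#'
#' Evaluates one estimation method on every kept segment of a
#' [segment_track()] result.
#'
#' Methods: `"mets"` — slope-adjusted METs, MET-hours = METs x hours,
#' VO2 (ml/kg) = MET-hours x 3.5 x 60; `"acsm_rw"` — piecewise ACSM rate
#' (ml/kg/min) x minutes; `"acsm_run"` — the ACSM running equation applied
#' at all segment speeds including walking ones (the speed-switched variant
#' is `"acsm_rw"`). MET-hours for the ACSM methods are the VO2-equivalent
#' MET-hours (VO2 / 210 ml/kg per MET-hour).
#'
#' @param kin a `track_kinematics` object from [segment_track()].
#' @param method `"mets"`, `"acsm_rw"` or `"acsm_run"`.
#' @param coef a [model_coefficients()].
#' @return A data.frame with one row per segment: `i_start`, `speed_kmh`,
#'   `slope_pct`, `mets_horizontal`, `cost_slope`, `mets_slope`,
#'   `met_hours`, `vo2_ml_per_kg`, `method`. The METs columns are `NA` for
#'   the ACSM methods.
#' @export
segment_energy <- function(kin, method = c("mets", "acsm_rw", "acsm_run"),
                           coef = model_coefficients()) {
  stopifnot(inherits(kin, "track_kinematics"))
  method <- match.arg(method)
  seg <- kin$segments
  if (nrow(seg) == 0L) stop("empty track: no segments left after filtering")
  hours <- seg$duration_s / 3600
  ml_per_met_hour <- coef$met_vo2_ml_kg_min * 60
  if (method == "mets") {
    mh <- mets_horizontal(seg$speed_kmh, coef)
    cs <- cost_of_slope(seg$slope_pct, coef)
    ms <- mh * cs
    met_hours <- ms * hours
    vo2 <- met_hours * ml_per_met_hour
  } else {
    rate_fun <- if (method == "acsm_rw") acsm_rw_vo2 else acsm_run_vo2
    rate <- rate_fun(seg$speed_kmh, seg$slope_pct / 100, coef)
    vo2 <- rate * (seg$duration_s / 60)
    met_hours <- vo2 / ml_per_met_hour
    mh <- cs <- ms <- NA_real_
  }
  data.frame(i_start = seg$i_start, speed_kmh = seg$speed_kmh,
             slope_pct = seg$slope_pct, mets_horizontal = mh,
             cost_slope = cs, mets_slope = ms, met_hours = met_hours,
             vo2_ml_per_kg = vo2, method = method)
}

#' Accumulate segment energy into an activity summary
#'
#' Sums per-segment exercise intensity over the whole recording: total
#' MET-hours, cumulative VO2 in ml/kg, and — when a body mass is supplied —
#' absolute VO2 in litres and energy expenditure in kcal (5 kcal per litre
#' of oxygen consumed).
#'
#' @param kin a `track_kinematics` from [segment_track()].
#' @param method `"mets"`, `"acsm_rw"` or `"acsm_run"` (see
#'   [segment_energy()]).
#' @param profile optional [athlete_profile()]; required for `vo2_l` and
#'   `energy_kcal`.
#' @param coef a [model_coefficients()].
#' @return An object of class `activity_summary`: `method`,
#'   `total_met_hours`, `vo2_ml_per_kg`, `vo2_l`, `energy_kcal` (the last
#'   two `NA` without a profile), `distance_m`, `duration_s`,
#'   `mean_speed_kmh`, `n_segments`.
#' @examples
#' b <- generate_track(leg_spec(10, 0, 360))
#' kin <- segment_track(b$track)
#' accumulate_energy(kin, "mets", athlete_profile(60))
#' @export
accumulate_energy <- function(kin, method = c("mets", "acsm_rw", "acsm_run"),
                              profile = NULL, coef = model_coefficients()) {
  method <- match.arg(method)
  per_seg <- segment_energy(kin, method, coef)
  vo2 <- sum(per_seg$vo2_ml_per_kg)
  met_hours <- sum(per_seg$met_hours)
  if (!is.null(profile) && !inherits(profile, "athlete_profile"))
    stop("`profile` must be an athlete_profile")
  vo2_l <- if (is.null(profile)) NA_real_ else vo2 * profile$body_mass_kg / 1000
  kcal <- if (is.null(profile)) NA_real_ else vo2_l * coef$kcal_per_l_o2
  structure(list(
    method = method,
    total_met_hours = met_hours,
    vo2_ml_per_kg = vo2,
    vo2_l = vo2_l,
    energy_kcal = kcal,
    distance_m = kin$total_distance_m,
    duration_s = kin$total_duration_s,
    mean_speed_kmh = (kin$total_distance_m / 1000) / (kin$total_duration_s / 3600),
    n_segments = nrow(per_seg)
  ), class = "activity_summary")
}

#' @export
print.activity_summary <- function(x, ...) {
  cat(sprintf("<activity_summary> method %s\n", x$method))
  cat(sprintf("  %.2f MET-h | VO2 %.1f ml/kg", x$total_met_hours, x$vo2_ml_per_kg))
  if (!is.na(x$vo2_l))
    cat(sprintf(" (%.2f L, %.1f kcal)", x$vo2_l, x$energy_kcal))
  cat(sprintf("\n  %.1f m in %.1f s (mean %.2f km/h, %d segments)\n",
              x$distance_m, x$duration_s, x$mean_speed_kmh, x$n_segments))
  invisible(x)
}

#' @export
as.data.frame.activity_summary <- function(x, ...) {
  data.frame(method = x$method, total_met_hours = x$total_met_hours,
             vo2_ml_per_kg = x$vo2_ml_per_kg, vo2_l = x$vo2_l,
             energy_kcal = x$energy_kcal, distance_m = x$distance_m,
             duration_s = x$duration_s, mean_speed_kmh = x$mean_speed_kmh,
             n_segments = x$n_segments)
}
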