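# Seeded synthetic GPS tracks with known speed/slope structure and
# closed-form expected energy outputs, so the full pipeline can be checked
# end to end without any real recording.

METERS_PER_DEG <- 2 * pi * EARTH_RADIUS_M / 360  # meridian arc, 111194.93 m

#' Course leg specification
#'
#' One constant-condition leg of a simulated course.
#'
#' @param speed_kmh 3-D (along-path) speed in km/h, > 0.
#' @param slope_pct constant slope in percent, within ±45 (the gradient-cost
#'   model's validity range).
#' @param duration_s leg duration in seconds, > 0.
#' @return An object of class `leg_spec`.
#' @examples
#' leg_spec(10, 0, 600)
#' @export
leg_spec <- function(speed_kmh, slope_pct, duration_s) {
  if (!is.numeric(speed_kmh) || length(speed_kmh) != 1L || speed_kmh <= 0)
    stop("`speed_kmh` must be a single positive number")
  if (!is.numeric(slope_pct) || length(slope_pct) != 1L ||
      abs(slope_pct) > 45)
    stop("`slope_pct` must be a single number within +/-45")
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("`duration_s` must be a single positive number")
  structure(list(speed_kmh = speed_kmh, slope_pct = slope_pct,
                 duration_s = duration_s), class = "leg_spec")
}

as_leg_list <- function(legs) {
  if (inherits(legs, "leg_spec")) legs <- list(legs)
  if (!is.list(legs) || length(legs) == 0L ||
      !all(vapply(legs, inherits, logical(1), "leg_spec")))
    stop("`legs` must be a non-empty list of leg_spec objects")
  legs
}

#' Generate a synthetic GPS track with known expected energy
#'
#' Lays out points along a meridian from the origin, one per sampling
#' interval. Per leg, the horizontal step is sized so that the 3-D speed
#' equals the specified speed and rise/run equals the specified slope
#' (consistent with the kinematics convention that speed uses the 3-D
#' distance); elevation integrates the vertical component. Optional
#' Gaussian noise (seeded) perturbs positions (applied in metres, converted
#' to degrees) and elevations. Leg durations are snapped to whole sampling
#' intervals so the analytic expectations are exact.
#'
#' Running along a meridian keeps the metre-to-degree conversion
#' latitude-independent, avoiding cos(latitude) confounds in tests.
#'
#' @param legs a [leg_spec()] or list of them.
#' @param sample_interval_s sampling interval in seconds (default 1, the
#'   cadence of wrist GPS devices).
#' @param noise_pos_m horizontal position noise SD in metres (default 0).
#' @param noise_ele_m elevation noise SD in metres (default 0).
#' @param seed integer seed governing all randomness in the bundle.
#' @param origin_lat,origin_lon start coordinates in degrees.
#' @param start_time POSIXct start of the recording (UTC).
#' @param name track name.
#' @return An object of class `synthetic_bundle`: `track` (a [track()]),
#'   `expected` (named list of [accumulate_energy()]-style
#'   `activity_summary` objects per method, computed analytically from the
#'   legs, noise-free), `legs`, `seed`, `noise_pos_m`, `noise_ele_m`,
#'   `sample_interval_s`.
#' @examples
#' b <- generate_track(list(leg_spec(10, 0, 600), leg_spec(6, 5, 300)))
#' b$expected$mets
#' @export
generate_track <- function(legs, sample_interval_s = 1, noise_pos_m = 0,
                           noise_ele_m = 0, seed = NULL,
                           origin_lat = 35, origin_lon = 139,
                           start_time = as.POSIXct("2024-06-01 09:00:00",
                                                   tz = "UTC"),
                           name = "synthetic course") {
  legs <- as_leg_list(legs)
  if (!is.numeric(sample_interval_s) || sample_interval_s <= 0)
    stop("`sample_interval_s` must be positive")
  if (noise_pos_m < 0 || noise_ele_m < 0) stop("noise SDs must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  lat <- origin_lat; lon <- origin_lon; ele <- 0
  for (leg in legs) {
    n_steps <- max(1L, as.integer(round(leg$duration_s / sample_interval_s)))
    v_ms <- leg$speed_kmh / 3.6
    step3d <- v_ms * sample_interval_s
    h_step <- step3d / sqrt(1 + (leg$slope_pct / 100)^2)
    v_step <- h_step * leg$slope_pct / 100
    lat <- c(lat, lat[length(lat)] + seq_len(n_steps) * h_step / METERS_PER_DEG)
    lon <- c(lon, rep(origin_lon, n_steps))
    ele <- c(ele, ele[length(ele)] + seq_len(n_steps) * v_step)
  }
  n <- length(lat)
  ts <- start_time + (seq_len(n) - 1L) * sample_interval_s
  if (noise_pos_m > 0) {
    lat <- lat + rnorm(n, 0, noise_pos_m) / METERS_PER_DEG
    lon <- lon + rnorm(n, 0, noise_pos_m) /
      (METERS_PER_DEG * cos(origin_lat * pi / 180))
  }
  if (noise_ele_m > 0) ele <- ele + rnorm(n, 0, noise_ele_m)

  trk <- track(data.frame(timestamp = ts, lat = lat, lon = lon, ele = ele),
               name = name, source = "synthetic")
  structure(list(track = trk,
                 expected = expected_summaries(legs, sample_interval_s),
                 legs = legs, seed = seed, noise_pos_m = noise_pos_m,
                 noise_ele_m = noise_ele_m,
                 sample_interval_s = sample_interval_s),
            class = "synthetic_bundle")
}

# Closed-form per-leg energy: constant speed/slope makes every model a
# simple rate x time sum. Durations snapped to whole intervals, matching
# generation.
expected_summaries <- function(legs, sample_interval_s,
                               coef = model_coefficients()) {
  v <- vapply(legs, `[[`, numeric(1), "speed_kmh")
  s <- vapply(legs, `[[`, numeric(1), "slope_pct")
  dur <- vapply(legs, function(l)
    max(1L, round(l$duration_s / sample_interval_s)) * sample_interval_s,
    numeric(1))
  distance_m <- sum(v / 3.6 * dur)
  total_s <- sum(dur)
  ml_per_met_hour <- coef$met_vo2_ml_kg_min * 60
  build <- function(method, vo2) {
    structure(list(method = method, total_met_hours = vo2 / ml_per_met_hour,
                   vo2_ml_per_kg = vo2, vo2_l = NA_real_,
                   energy_kcal = NA_real_, distance_m = distance_m,
                   duration_s = total_s,
                   mean_speed_kmh = (distance_m / 1000) / (total_s / 3600),
                   n_segments = as.integer(round(sum(dur / sample_interval_s)))),
              class = "activity_summary")
  }
  list(
    mets = build("mets",
                 sum(mets_on_slope(v, s, coef) * (dur / 3600)) * ml_per_met_hour),
    acsm_rw = build("acsm_rw", sum(acsm_rw_vo2(v, s / 100, coef) * dur / 60)),
    acsm_run = build("acsm_run", sum(acsm_run_vo2(v, s / 100, coef) * dur / 60))
  )
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("<synthetic_bundle> %d leg(s), %d points, noise pos %.2g m / ele %.2g m%s\n",
              length(x$legs), n_points(x$track), x$noise_pos_m, x$noise_ele_m,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' End-to-end pipeline check against analytic expectations
#'
#' Runs [segment_track()] and [accumulate_energy()] on a synthetic bundle's
#' track for each method and reports the relative deviation of the
#' pipeline's cumulative VO2 from the bundle's closed-form expectation.
#' Deviations beyond the tolerance are flagged in the report, not raised —
#' noisy bundles are expected to deviate.
#'
#' @param bundle a [generate_track()] result.
#' @param tolerance_rel relative tolerance used for the `ok` flag
#'   (default 1e-3).
#' @return A data.frame with one row per method: `method`,
#'   `expected_vo2_ml_per_kg`, `observed_vo2_ml_per_kg`, `rel_deviation`,
#'   `ok`; attribute `max_rel_deviation`.
#' @export
pipeline_roundtrip_check <- function(bundle, tolerance_rel = 1e-3) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  kin <- segment_track(bundle$track)
  rows <- lapply(names(bundle$expected), function(m) {
    obs <- accumulate_energy(kin, m)
    exp_vo2 <- bundle$expected[[m]]$vo2_ml_per_kg
    dev <- abs(obs$vo2_ml_per_kg - exp_vo2) / exp_vo2
    data.frame(method = m, expected_vo2_ml_per_kg = exp_vo2,
               observed_vo2_ml_per_kg = obs$vo2_ml_per_kg,
               rel_deviation = dev, ok = dev <= tolerance_rel)
  })
  out <- do.call(rbind, rows)
  attr(out, "max_rel_deviation") <- max(out$rel_deviation)
  attr(out, "tolerance_rel") <- tolerance_rel
  out
}
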