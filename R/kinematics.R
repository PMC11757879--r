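# Track -> segments: distance, duration, speed, slope between adjacent
# points. Speed uses the 3-D distance actually travelled; slope uses the
# horizontal distance as denominator (rise over run, in percent).

EARTH_RADIUS_M <- 6371000

#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6,371,000 m. At the sub-10 m
#' hops of 1 Hz walking/running tracks, the spherical-vs-planar discrepancy
#' is far below GPS noise, so this serves as the horizontal component of
#' segment distances.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorised).
#' @return Distance(s) in metres.
#' @examples
#' haversine_m(0, 0, 0, 1)   # one degree of longitude at the equator
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M)
}

#' Segment a track into adjacent-point kinematics
#'
#' Every adjacent pair of points becomes one segment carrying horizontal and
#' 3-D distance, duration, speed (km/h, from the 3-D distance) and slope
#' (percent, 100 x vertical / horizontal). Degenerate pairs are dropped and
#' counted rather than erroring: zero-duration segments (duplicate device
#' timestamps) and implausibly fast segments (GPS "teleports" above
#' `outlier_speed_max_kmh`).
#'
#' @param x a [track()] with elevation on every point (annotate first if
#'   needed; see [annotate_track()]).
#' @param outlier_speed_max_kmh drop segments faster than this (default
#'   40 km/h, above any human running speed).
#' @param slope_clip_pct slope assigned (with the sign of the vertical step)
#'   when the horizontal distance is zero but elevation changes; matches the
#'   gradient-cost model's validity bound so elevator-like artifacts cannot
#'   produce unbounded cost.
#' @return An object of class `track_kinematics`: list with `segments`
#'   (data.frame: `i_start`, `i_end`, `horizontal_m`, `vertical_m`,
#'   `distance3d_m`, `duration_s`, `speed_kmh`, `slope_pct`),
#'   `n_dropped_zero_duration`, `n_dropped_outlier`, `total_distance_m`,
#'   `total_duration_s`, `elevation_gain_m` (sum of positive vertical
#'   steps). Totals are over kept segments.
#' @export
segment_track <- function(x, outlier_speed_max_kmh = 40,
                          slope_clip_pct = model_coefficients()$slope_clip_pct) {
  stopifnot(inherits(x, "track"))
  p <- x$points
  if (nrow(p) < 2L) stop("empty track: need at least 2 points to segment")
  missing_ele <- which(is.na(p$ele))
  if (length(missing_ele))
    stop("elevation absent at point(s) ",
         paste(utils::head(missing_ele, 10L), collapse = ", "),
         "; annotate the track first")
  n <- nrow(p)
  i <- seq_len(n - 1L)
  horizontal <- haversine_m(p$lat[i], p$lon[i], p$lat[i + 1L], p$lon[i + 1L])
  vertical <- p$ele[i + 1L] - p$ele[i]
  d3 <- sqrt(horizontal^2 + vertical^2)
  dt <- as.numeric(difftime(p$timestamp[i + 1L], p$timestamp[i], units = "secs"))
  seg <- data.frame(i_start = i, i_end = i + 1L, horizontal_m = horizontal,
                    vertical_m = vertical, distance3d_m = d3, duration_s = dt)
  keep <- seg$duration_s > 0
  n_zero <- sum(!keep)
  if (n_zero) message("dropped ", n_zero, " zero-duration segment(s)")
  seg <- seg[keep, , drop = FALSE]
  seg$speed_kmh <- (seg$distance3d_m / 1000) / (seg$duration_s / 3600)
  fast <- seg$speed_kmh > outlier_speed_max_kmh
  n_outlier <- sum(fast)
  if (n_outlier)
    message("dropped ", n_outlier, " outlier segment(s) above ",
            outlier_speed_max_kmh, " km/h")
  seg <- seg[!fast, , drop = FALSE]
  slope <- ifelse(seg$horizontal_m > 0,
                  100 * seg$vertical_m / seg$horizontal_m,
                  sign(seg$vertical_m) * slope_clip_pct)
  seg$slope_pct <- slope
  rownames(seg) <- NULL
  structure(list(
    segments = seg,
    n_dropped_zero_duration = n_zero,
    n_dropped_outlier = n_outlier,
    total_distance_m = sum(seg$distance3d_m),
    total_duration_s = sum(seg$duration_s),
    elevation_gain_m = sum(pmax(seg$vertical_m, 0))
  ), class = "track_kinematics")
}

#' @export
print.track_kinematics <- function(x, ...) {
  cat(sprintf("<track_kinematics> %d segments, %.1f m over %.1f s (gain %.1f m)\n",
              nrow(x$segments), x$total_distance_m, x$total_duration_s,
              x$elevation_gain_m))
  if (x$n_dropped_zero_duration || x$n_dropped_outlier)
    cat(sprintf("  dropped: %d zero-duration, %d outlier\n",
                x$n_dropped_zero_duration, x$n_dropped_outlier))
  invisible(x)
}

#' @export
as.data.frame.track_kinematics <- function(x, ...) x$segments

#' Moving-median elevation smoothing
#'
#' Centred moving median over elevations with window truncation at the track
#' ends; `window = 1` is the identity. Off by default throughout the
#' pipeline — the energy models are applied to raw device/provider
#' elevations unless the user opts in.
#'
#' @param x a [track()].
#' @param window odd window length, >= 1.
#' @return A new [track()] with smoothed elevations.
#' @export
smooth_elevation <- function(x, window) {
  stopifnot(inherits(x, "track"))
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window != round(window) || window %% 2 == 0)
    stop("`window` must be an odd integer >= 1")
  if (window == 1) return(x)
  ele <- x$points$ele
  n <- length(ele)
  half <- (window - 1) / 2
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::median(ele[lo:hi])
  }, numeric(1))
  out <- x
  out$points$ele <- sm
  out
}
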