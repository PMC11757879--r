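#' Construct a GPS track
#'
#' A track is an ordered sequence of timestamped geodetic positions with
#' optional elevation — the raw input stream of the whole pipeline. The
#' constructor validates coordinate bounds and timestamp ordering; it never
#' reorders points.
#'
#' @param points a data.frame with columns `timestamp` (POSIXct, UTC),
#'   `lat` (degrees, WGS84, in \[-90, 90\]), `lon` (degrees, in
#'   \[-180, 180\]) and optionally `ele` (metres; `NA` where elevation is
#'   absent).
#' @param name free-text track name.
#' @param source one of `"gpx"`, `"csv"`, `"synthetic"`.
#'
#' @return An object of class `track`: a list with elements `points`,
#'   `name`, `source`.
#'
#' @details Timestamps must be non-decreasing; duplicate consecutive
#'   timestamps are kept (zero-duration segments are dropped later by
#'   [segment_track()]), so construction stays non-destructive. At least one
#'   point is required; kinematic computations additionally require two.
#'
#' @examples
#' pts <- data.frame(
#'   timestamp = as.POSIXct("2024-06-01 09:00:00", tz = "UTC") + 0:2,
#'   lat = 35 + (0:2) * 1e-5, lon = 139, ele = c(10, 10.5, 11)
#' )
#' track(pts, name = "demo")
#' @export
track <- function(points, name = "", source = c("synthetic", "gpx", "csv")) {
  source <- match.arg(source)
  if (!is.data.frame(points)) stop("`points` must be a data.frame")
  required <- c("timestamp", "lat", "lon")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols))
    stop("track points missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(points) == 0L) stop("empty track: no points")
  if (!inherits(points$timestamp, "POSIXct"))
    stop("`timestamp` must be POSIXct")
  attr(points$timestamp, "tzone") <- "UTC"
  if (anyNA(points$timestamp)) stop("track contains unparseable timestamps")
  if (!"ele" %in% names(points)) points$ele <- NA_real_
  points <- points[, c("timestamp", "lat", "lon", "ele")]
  points$lat <- as.numeric(points$lat)
  points$lon <- as.numeric(points$lon)
  points$ele <- as.numeric(points$ele)
  if (anyNA(points$lat) || anyNA(points$lon))
    stop("track contains missing coordinates")
  bad_lat <- which(points$lat < -90 | points$lat > 90)
  if (length(bad_lat)) stop("latitude out of [-90, 90] at point ", bad_lat[1L])
  bad_lon <- which(points$lon < -180 | points$lon > 180)
  if (length(bad_lon)) stop("longitude out of [-180, 180] at point ", bad_lon[1L])
  dt <- diff(as.numeric(points$timestamp))
  bad_order <- which(dt < 0)
  if (length(bad_order))
    stop("timestamps out of order at point ", bad_order[1L] + 1L)
  rownames(points) <- NULL
  structure(list(points = points, name = name, source = source),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  n <- nrow(x$points)
  cat(sprintf("<track> %s (%s), %d point%s\n",
              if (nzchar(x$name)) x$name else "<unnamed>", x$source,
              n, if (n == 1L) "" else "s"))
  if (n) {
    span <- as.numeric(difftime(x$points$timestamp[n], x$points$timestamp[1L],
                                units = "secs"))
    cat(sprintf("  start %s, span %.1f s, elevation %s\n",
                format(x$points$timestamp[1L], "%Y-%m-%dT%H:%M:%OS3Z"), span,
                if (anyNA(x$points$ele)) sprintf("absent on %d point(s)",
                                                 sum(is.na(x$points$ele)))
                else "present"))
  }
  invisible(x)
}

#' Number of points in a track
#' @param x a [track()].
#' @return Integer point count.
#' @export
n_points <- function(x) {
  stopifnot(inherits(x, "track"))
  nrow(x$points)
}

#' Athlete profile
#'
#' Body mass as worn (apparatus, shoes and gear included) — the mass that
#' converts mass-specific VO2 (ml/kg) into absolute volume (L) and energy
#' (kcal).
#'
#' @param body_mass_kg body mass in kg; must lie in (20, 300), with a warning
#'   outside (40, 150).
#' @param id free-text identifier.
#' @return An object of class `athlete_profile`.
#' @examples
#' athlete_profile(61.7, id = "participant")
#' @export
athlete_profile <- function(body_mass_kg, id = "") {
  if (!is.numeric(body_mass_kg) || length(body_mass_kg) != 1L ||
      is.na(body_mass_kg) || body_mass_kg <= 20 || body_mass_kg >= 300)
    stop("`body_mass_kg` must be a single number in (20, 300)")
  if (body_mass_kg <= 40 || body_mass_kg >= 150)
    warning("body mass ", body_mass_kg, " kg is outside the usual (40, 150) range")
  structure(list(body_mass_kg = body_mass_kg, id = id),
            class = "athlete_profile")
}
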