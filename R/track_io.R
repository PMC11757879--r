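# Track I/O: GPX 1.1 read/write and a plain CSV dialect
# (columns timestamp,lat,lon,elevation_m; RFC 4180, UTF-8).

# Parse ISO 8601 timestamps to POSIXct UTC. Accepts 'Z', '+hh:mm'/'-hhmm'
# offsets, fractional seconds, and 'T' or space separators. Naive stamps
# (no designator) are taken as UTC; `warn_naive` flags them (CSV input).
parse_iso_time <- function(x, warn_naive = FALSE) {
  x <- trimws(as.character(x))
  out <- rep(as.POSIXct(NA), length(x))
  off_re <- "([+-])([0-9]{2}):?([0-9]{2})$"
  has_z <- grepl("[Zz]$", x)
  has_off <- !has_z & grepl(off_re, x)
  naive <- !has_z & !has_off & nzchar(x)
  if (warn_naive && any(naive))
    warning(sum(naive), " timestamp(s) carry no timezone designator; assuming UTC")
  body <- x
  body[has_z] <- sub("[Zz]$", "", body[has_z])
  body[has_off] <- sub(off_re, "", body[has_off])
  body <- sub("T", " ", body, fixed = TRUE)
  parsed <- as.POSIXct(body, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  # no-seconds variant, e.g. "2024-06-01 09:00"
  retry <- is.na(parsed) & nzchar(body)
  if (any(retry))
    parsed[retry] <- as.POSIXct(body[retry], tz = "UTC", format = "%Y-%m-%d %H:%M")
  offset_s <- numeric(length(x))
  if (any(has_off)) {
    sgn <- ifelse(sub(paste0(".*", off_re), "\\1", x[has_off]) == "+", 1, -1)
    hh <- as.numeric(sub(paste0(".*", off_re), "\\2", x[has_off]))
    mm <- as.numeric(sub(paste0(".*", off_re), "\\3", x[has_off]))
    offset_s[has_off] <- sgn * (hh * 3600 + mm * 60)
  }
  out <- parsed - offset_s
  attr(out, "tzone") <- "UTC"
  out
}

format_iso_time <- function(t) {
  # millisecond precision, always UTC with 'Z'
  format(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
}

#' Read a GPS track from a GPX 1.1 file
#'
#' Reads the first `<trk>` element; `<trkpt>` latitude/longitude attributes
#' and the `<ele>` and `<time>` children map onto track points. Multiple
#' `<trkseg>` children are concatenated in file order (a recorded activity is
#' one continuous stream); a note reports the segment boundaries. Route
#' (`<rte>`) and waypoint (`<wpt>`) elements are ignored.
#'
#' @param path path to a GPX file.
#' @return A [track()] with `source = "gpx"`. Points missing `<ele>` get an
#'   absent (`NA`) elevation; points missing `<time>` are an error (the
#'   pipeline is time-based).
#' @examples
#' gpx <- tempfile(fileext = ".gpx")
#' writeLines(c(
#'   '<?xml version="1.0"?><gpx version="1.1"><trk><trkseg>',
#'   '<trkpt lat="35.0" lon="139.0"><ele>12.0</ele>',
#'   '<time>2024-06-01T09:00:00Z</time></trkpt>',
#'   '<trkpt lat="35.00001" lon="139.0"><ele>12.1</ele>',
#'   '<time>2024-06-01T09:00:01Z</time></trkpt>',
#'   '</trkseg></trk></gpx>'), gpx)
#' read_gpx(gpx)
#' @export
read_gpx <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  trk <- xml2::xml_find_first(doc, ".//trk")
  if (inherits(trk, "xml_missing")) stop("empty track: no <trk> element in ", path)
  segs <- xml2::xml_find_all(trk, ".//trkseg")
  pts <- xml2::xml_find_all(trk, ".//trkpt")
  if (length(pts) == 0L) stop("empty track: no trackpoints in ", path)
  if (length(segs) > 1L) {
    sizes <- vapply(segs, function(s) length(xml2::xml_find_all(s, ".//trkpt")),
                    integer(1))
    message("concatenating ", length(segs), " track segments (boundaries after points ",
            paste(cumsum(sizes)[-length(sizes)], collapse = ", "), ")")
  }
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  time_raw <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
  no_time <- which(is.na(time_raw) | !nzchar(time_raw))
  if (length(no_time))
    stop("trackpoint ", no_time[1L], " has no <time> element")
  ts <- parse_iso_time(time_raw)
  bad_ts <- which(is.na(ts))
  if (length(bad_ts))
    stop("trackpoint ", bad_ts[1L], " has unparseable <time> '",
         time_raw[bad_ts[1L]], "'")
  ele <- suppressWarnings(as.numeric(
    xml2::xml_text(xml2::xml_find_first(pts, "./ele"))))
  name <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
  track(data.frame(timestamp = ts, lat = lat, lon = lon, ele = ele),
        name = if (is.na(name)) "" else name, source = "gpx")
}

#' Write a track as GPX 1.1
#'
#' @param x a [track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @details Coordinates are written to 1e-7 degrees, elevations to 0.01 m,
#'   timestamps to 1 ms (UTC, `Z`-suffixed); points with absent elevation
#'   omit `<ele>`.
#' @export
write_gpx <- function(x, path) {
  stopifnot(inherits(x, "track"))
  p <- x$points
  if (nrow(p) == 0L) stop("empty track: refusing to write")
  ele_tag <- ifelse(is.na(p$ele), "",
                    sprintf("<ele>%.2f</ele>", p$ele))
  body <- sprintf('      <trkpt lat="%.7f" lon="%.7f">%s<time>%s</time></trkpt>',
                  p$lat, p$lon, ele_tag, format_iso_time(p$timestamp))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gpx version="1.1" creator="gpsmets" xmlns="http://www.topografix.com/GPX/1/1">',
    "  <trk>",
    sprintf("    <name>%s</name>", x$name),
    "    <trkseg>",
    body,
    "    </trkseg>",
    "  </trk>",
    "</gpx>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a track from CSV
#'
#' Expects a header row with columns `timestamp`, `lat`, `lon` and optionally
#' `elevation_m` (or `elevation`); RFC 4180, UTF-8. Timestamps must be
#' ISO 8601; stamps without a timezone designator are assumed UTC with a
#' warning.
#'
#' @param path path to the CSV file.
#' @return A [track()] with `source = "csv"`.
#' @export
read_track_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  names(raw) <- tolower(trimws(names(raw)))
  if ("elevation" %in% names(raw) && !"elevation_m" %in% names(raw))
    names(raw)[names(raw) == "elevation"] <- "elevation_m"
  missing_cols <- setdiff(c("timestamp", "lat", "lon"), names(raw))
  if (length(missing_cols))
    stop("CSV schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) stop("empty track: no data rows in ", path)
  ts <- parse_iso_time(raw$timestamp, warn_naive = TRUE)
  bad <- which(is.na(ts))
  if (length(bad))
    stop("unparseable timestamp on data line ", bad[1L], ": '",
         raw$timestamp[bad[1L]], "'")
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(raw[[col]])))
    if (length(bad))
      stop("unparseable ", col, " on data line ", bad[1L], ": '",
           raw[[col]][bad[1L]], "'")
    v
  }
  lat <- num("lat"); lon <- num("lon")
  if (anyNA(lat) || anyNA(lon))
    stop("missing coordinate on data line ",
         which(is.na(lat) | is.na(lon))[1L])
  ele <- if ("elevation_m" %in% names(raw)) num("elevation_m") else NA_real_
  track(data.frame(timestamp = ts, lat = lat, lon = lon, ele = ele),
        source = "csv")
}

#' Write a track as CSV
#'
#' Columns `timestamp,lat,lon,elevation_m`; lossless round trip with
#' [read_track_csv()] to 1e-7 degrees, 0.01 m and 1 ms, and byte-stable on
#' re-write (fixed formatting).
#'
#' @param x a [track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(x, path) {
  stopifnot(inherits(x, "track"))
  p <- x$points
  if (nrow(p) == 0L) stop("empty track: refusing to write")
  lines <- c("timestamp,lat,lon,elevation_m",
             sprintf("%s,%.7f,%.7f,%s",
                     format_iso_time(p$timestamp), p$lat, p$lon,
                     ifelse(is.na(p$ele), "", sprintf("%.2f", p$ele))))
  con <- tryCatch(suppressWarnings(file(path, open = "wb")),
                  error = function(e) stop("cannot open ", path, " for writing",
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
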