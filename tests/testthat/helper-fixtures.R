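# Shared fixture builders: tiny tracks, GPX text, elevation grids.

t0 <- as.POSIXct("2024-06-01 09:00:00", tz = "UTC")

make_points <- function(n, lat0 = 35, lon0 = 139, ele = 0,
                        dt = 1, dlat = 1e-5) {
  data.frame(
    timestamp = t0 + (seq_len(n) - 1) * dt,
    lat = lat0 + (seq_len(n) - 1) * dlat,
    lon = lon0,
    ele = rep_len(ele, n)
  )
}

# A flat two-point track a given horizontal distance (m) and duration (s)
# apart, along a meridian, with optional elevation step.
two_point_track <- function(horizontal_m, duration_s, vertical_m = 0,
                            ele0 = 100) {
  m_per_deg <- 2 * pi * 6371000 / 360
  track(data.frame(
    timestamp = t0 + c(0, duration_s),
    lat = c(35, 35 + horizontal_m / m_per_deg),
    lon = 139,
    ele = c(ele0, ele0 + vertical_m)
  ))
}

gpx_text <- function(lat, lon, ele = NULL, time = NULL, extra_seg_at = NULL) {
  pt <- function(i) {
    paste0('<trkpt lat="', lat[i], '" lon="', lon[i], '">',
           if (!is.null(ele) && !is.na(ele[i]))
             paste0("<ele>", ele[i], "</ele>") else "",
           if (!is.null(time) && !is.na(time[i]))
             paste0("<time>", time[i], "</time>") else "",
           "</trkpt>")
  }
  body <- vapply(seq_along(lat), pt, character(1))
  if (!is.null(extra_seg_at)) {
    body <- c(body[seq_len(extra_seg_at)], "</trkseg><trkseg>",
              body[-seq_len(extra_seg_at)])
  }
  paste0('<?xml version="1.0" encoding="UTF-8"?>',
         '<gpx version="1.1" xmlns="http://www.topografix.com/GPX/1/1">',
         "<trk><name>fixture</name><trkseg>",
         paste(body, collapse = ""),
         "</trkseg></trk></gpx>")
}

write_tmp <- function(text, ext) {
  path <- tempfile(fileext = ext)
  writeLines(text, path)
  path
}

iso_times <- function(n, dt = 1) {
  format(t0 + (seq_len(n) - 1) * dt, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

# Plane grid: z = 100 * (lat - origin_lat) / cell_deg, independent of lon.
plane_grid <- function(nrow = 5, ncol = 5, origin_lat = 34.9,
                       origin_lon = 138.9, cell_deg = 0.05) {
  vals <- matrix(rep(100 * (seq_len(nrow) - 1), ncol), nrow = nrow)
  elevation_grid(vals, origin_lat, origin_lon, cell_deg)
}
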