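test_that("track constructor validates bounds, ordering and emptiness", {
  expect_s3_class(track(make_points(3)), "track")
  expect_error(track(data.frame(timestamp = t0[0], lat = numeric(),
                                lon = numeric())), "empty track")
  bad <- make_points(3); bad$lat[2] <- 91
  expect_error(track(bad), "latitude.*point 2")
  bad <- make_points(3); bad$lon[3] <- -181
  expect_error(track(bad), "longitude.*point 3")
  bad <- make_points(3); bad$timestamp[3] <- bad$timestamp[1]
  expect_error(track(bad), "out of order at point 3")
  # duplicate consecutive timestamps are kept, not an error
  dup <- make_points(3); dup$timestamp[2] <- dup$timestamp[1]
  expect_equal(n_points(track(dup)), 3)
  no_ele <- make_points(2)[, c("timestamp", "lat", "lon")]
  expect_true(all(is.na(track(no_ele)$points$ele)))
})

test_that("athlete profile enforces mass bounds with a soft warning band", {
  expect_equal(athlete_profile(61.7)$body_mass_kg, 61.7)
  expect_warning(athlete_profile(35), "outside the usual")
  expect_error(athlete_profile(10), "20, 300")
  expect_error(athlete_profile(-5))
})

test_that("GPX parsing maps trkpt attributes and children onto points", {
  path <- write_tmp(gpx_text(lat = c(35, 35.00001, 35.00002), lon = rep(139, 3),
                             ele = c(10, 10.5, 11), time = iso_times(3)), ".gpx")
  trk <- read_gpx(path)
  expect_equal(n_points(trk), 3)
  expect_equal(trk$source, "gpx")
  expect_equal(trk$points$ele, c(10, 10.5, 11))
  expect_equal(as.numeric(diff(trk$points$timestamp), units = "secs"), c(1, 1))
  expect_equal(trk$name, "fixture")
})

test_that("GPX parsing rejects malformed, empty and ill-timed files", {
  expect_error(read_gpx(write_tmp("<gpx><trk>", ".gpx")), "malformed XML")
  expect_error(read_gpx(write_tmp(
    '<gpx version="1.1"><trk><trkseg></trkseg></trk></gpx>', ".gpx")),
    "empty track")
  # missing <time> on point 2 names the index
  path <- write_tmp(gpx_text(lat = c(35, 35.1), lon = c(139, 139),
                             time = c(iso_times(1), NA)), ".gpx")
  expect_error(read_gpx(path), "trackpoint 2 has no <time>")
  # non-monotone timestamps name the offending point
  path <- write_tmp(gpx_text(lat = c(35, 35.1, 35.2), lon = rep(139, 3),
                             time = iso_times(3)[c(1, 3, 2)]), ".gpx")
  expect_error(read_gpx(path), "out of order at point 3")
})

test_that("GPX with missing <ele> yields absent elevation, and trksegs concatenate", {
  path <- write_tmp(gpx_text(lat = c(35, 35.1, 35.2), lon = rep(139, 3),
                             ele = c(10, NA, 12), time = iso_times(3),
                             extra_seg_at = 2), ".gpx")
  expect_message(trk <- read_gpx(path), "concatenating 2 track segments")
  expect_equal(is.na(trk$points$ele), c(FALSE, TRUE, FALSE))
  expect_equal(n_points(trk), 3)
})

test_that("CSV read enforces schema, ordering and parseability", {
  path <- write_tmp(c("timestamp,lat,lon,elevation_m",
                      paste0(iso_times(2), ",35.0,139.0,10")), ".csv")
  trk <- read_track_csv(path)
  expect_equal(n_points(trk), 2)
  expect_equal(trk$source, "csv")
  # elevation column optional
  path <- write_tmp(c("timestamp,lat,lon",
                      paste0(iso_times(2), ",35.0,139.0")), ".csv")
  expect_true(all(is.na(read_track_csv(path)$points$ele)))
  expect_error(read_track_csv(write_tmp(c("timestamp,lat", "x,1"), ".csv")),
               "missing column")
  path <- write_tmp(c("timestamp,lat,lon",
                      paste0(iso_times(2)[c(2, 1)], ",35.0,139.0")), ".csv")
  expect_error(read_track_csv(path), "out of order")
  path <- write_tmp(c("timestamp,lat,lon", "2024-06-01T09:00:00Z,abc,139"),
                    ".csv")
  expect_error(read_track_csv(path), "line 1")
})

test_that("naive and offset CSV timestamps resolve to UTC", {
  path <- write_tmp(c("timestamp,lat,lon,elevation_m",
                      "2024-06-01 09:00:00,35,139,1",
                      "2024-06-01 09:00:01,35,139,1"), ".csv")
  expect_warning(trk <- read_track_csv(path), "assuming UTC")
  expect_equal(trk$points$timestamp[1], t0)
  path <- write_tmp(c("timestamp,lat,lon,elevation_m",
                      "2024-06-01T18:00:00+09:00,35,139,1",
                      "2024-06-01T18:00:01+09:00,35,139,1"), ".csv")
  trk <- read_track_csv(path)
  expect_equal(trk$points$timestamp[1], t0)
})

test_that("write/read round trips are lossless at the stated precisions", {
  set.seed(42)
  n <- 200
  pts <- data.frame(
    timestamp = t0 + cumsum(runif(n, 0.5, 2)),
    lat = 35 + cumsum(rnorm(n, 1e-5, 1e-6)),
    lon = 139 + cumsum(rnorm(n, 0, 1e-6)),
    ele = 100 + cumsum(rnorm(n, 0, 0.2))
  )
  trk <- track(pts, name = "rt", source = "synthetic")
  csv <- tempfile(fileext = ".csv")
  write_track_csv(trk, csv)
  back <- read_track_csv(csv)
  expect_equal(back$points$lat, trk$points$lat, tolerance = 1e-7)
  expect_equal(back$points$lon, trk$points$lon, tolerance = 1e-7)
  expect_equal(back$points$ele, trk$points$ele, tolerance = 0.01)
  expect_true(all(abs(as.numeric(back$points$timestamp) -
                      as.numeric(trk$points$timestamp)) <= 1e-3 + 1e-9))
  # GPX round trip at the same precisions
  gpx <- tempfile(fileext = ".gpx")
  write_gpx(trk, gpx)
  back_gpx <- read_gpx(gpx)
  expect_equal(back_gpx$points$lat, trk$points$lat, tolerance = 1e-7)
  expect_equal(back_gpx$points$ele, trk$points$ele, tolerance = 0.01)
})

test_that("re-writing a read-back CSV is a byte-stable fixed point", {
  b <- generate_track(leg_spec(10, 2, 2000), noise_pos_m = 1, noise_ele_m = 0.5,
                      seed = 7)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_track_csv(b$track, f1)
  write_track_csv(read_track_csv(f1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("writers refuse an empty track and unwritable paths", {
  trk <- track(make_points(2))
  expect_error(write_track_csv(trk, file.path(tempdir(), "no/such/dir/x.csv")),
               "cannot open")
  trk$points <- trk$points[0, ]
  expect_error(write_track_csv(trk, tempfile()), "empty track")
  expect_error(write_gpx(trk, tempfile()), "empty track")
})
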