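# Elevation providers. The core pipeline never touches the network: any
# function(lat, lon) -> elevation (NA when not covered) satisfies the
# provider contract, and an in-memory raster grid implements it offline.
# A thin adapter around a web altitude API can satisfy the same contract.

#' In-memory raster elevation grid
#'
#' A rectangular grid of elevations with cell centres at
#' `origin_lat + (i-1)*cell_deg`, `origin_lon + (j-1)*cell_deg` for
#' `values[i, j]`. Serves as an offline digital elevation model for
#' annotating tracks.
#'
#' @param values numeric matrix of elevations (metres); at least 2 x 2,
#'   all finite. Rows index latitude, columns longitude.
#' @param origin_lat,origin_lon degrees of the centre of cell \[1, 1\].
#' @param cell_deg degrees per cell, > 0.
#' @return An object of class `elevation_grid`.
#' @examples
#' g <- elevation_grid(matrix(100, 4, 4), 35, 139, 0.01)
#' grid_lookup(g, 35.015, 139.02)
#' @export
elevation_grid <- function(values, origin_lat, origin_lon, cell_deg) {
  if (!is.matrix(values) || nrow(values) < 2L || ncol(values) < 2L)
    stop("`values` must be a matrix of at least 2 x 2 cells")
  if (!all(is.finite(values))) stop("grid values must all be finite")
  if (!is.numeric(cell_deg) || length(cell_deg) != 1L || cell_deg <= 0)
    stop("`cell_deg` must be a single positive number")
  structure(list(values = values, origin_lat = origin_lat,
                 origin_lon = origin_lon, cell_deg = cell_deg),
            class = "elevation_grid")
}

#' Read an elevation grid from a simple CSV dialect
#'
#' The format is deliberately minimal: a first line
#' `origin_lat,origin_lon,cell_deg` with its three values on the second
#' line, then one comma-separated row of elevations per grid latitude row.
#'
#' @param path path to the grid file.
#' @return An [elevation_grid()].
#' @export
read_elevation_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 4L) stop("grid file too short: need header + >=2 value rows")
  hdr <- tolower(trimws(strsplit(lines[1L], ",")[[1L]]))
  if (!identical(hdr, c("origin_lat", "origin_lon", "cell_deg")))
    stop("grid header must be 'origin_lat,origin_lon,cell_deg'")
  meta <- as.numeric(strsplit(lines[2L], ",")[[1L]])
  if (length(meta) != 3L || anyNA(meta)) stop("unparseable grid metadata line")
  rows <- lapply(lines[-(1:2)], function(l) as.numeric(strsplit(l, ",")[[1L]]))
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1L) stop("ragged grid: value rows differ in length")
  values <- do.call(rbind, rows)
  if (anyNA(values)) stop("unparseable grid value")
  elevation_grid(values, meta[1L], meta[2L], meta[3L])
}

#' Query an elevation grid at a coordinate
#'
#' Bilinear interpolation among the four surrounding cell centres (the
#' default), or nearest-neighbour. Queries outside the grid's cell-centre
#' bounding box return `NA` — a not-covered signal, not an error — so
#' callers can fall back to device elevation.
#'
#' @param grid an [elevation_grid()].
#' @param lat,lon query coordinates in degrees (vectorised).
#' @param method `"bilinear"` or `"nearest"`.
#' @return Elevations in metres; `NA` where not covered.
#' @export
grid_lookup <- function(grid, lat, lon, method = c("bilinear", "nearest")) {
  stopifnot(inherits(grid, "elevation_grid"))
  method <- match.arg(method)
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  v <- grid$values
  ri <- (lat - grid$origin_lat) / grid$cell_deg   # 0-based fractional row
  ci <- (lon - grid$origin_lon) / grid$cell_deg
  out <- rep(NA_real_, n)
  eps <- 1e-9
  inside <- ri >= -eps & ri <= nrow(v) - 1 + eps &
            ci >= -eps & ci <= ncol(v) - 1 + eps
  if (!any(inside)) return(out)
  ri <- pmin(pmax(ri, 0), nrow(v) - 1)
  ci <- pmin(pmax(ci, 0), ncol(v) - 1)
  if (method == "nearest") {
    out[inside] <- v[cbind(round(ri[inside]) + 1L, round(ci[inside]) + 1L)]
    return(out)
  }
  i0 <- pmin(floor(ri), nrow(v) - 2); j0 <- pmin(floor(ci), ncol(v) - 2)
  fr <- ri - i0; fc <- ci - j0
  idx <- function(di, dj) v[cbind(i0 + di + 1L, j0 + dj + 1L)[inside, , drop = FALSE]]
  out[inside] <- (1 - fr[inside]) * (1 - fc[inside]) * idx(0, 0) +
                 (1 - fr[inside]) * fc[inside]       * idx(0, 1) +
                 fr[inside]       * (1 - fc[inside]) * idx(1, 0) +
                 fr[inside]       * fc[inside]       * idx(1, 1)
  out
}

#' Make an elevation provider from a grid
#'
#' Wraps an [elevation_grid()] into the provider contract used by
#' [annotate_track()]: a deterministic `function(lat, lon)` returning
#' elevations, `NA` where the grid does not cover the query.
#'
#' @inheritParams grid_lookup
#' @return A function `(lat, lon) -> elevation_m`.
#' @export
grid_provider <- function(grid, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  force(grid)
  function(lat, lon) grid_lookup(grid, lat, lon, method = method)
}

#' Annotate a track with provider elevations
#'
#' @param x a [track()].
#' @param provider a `function(lat, lon) -> elevation_m` (e.g.
#'   [grid_provider()]); must return `NA` for coordinates it cannot cover.
#' @param policy `"fill_missing"` sets elevation only where absent (device
#'   elevations are treated as authoritative); `"override_all"` replaces
#'   every elevation the provider covers. Points the provider cannot cover
#'   retain their prior elevation.
#' @return A new [track()] with elevations set. If any point still lacks
#'   elevation afterwards, an error lists the offending indices (slope
#'   cannot be computed without elevation).
#' @details `fill_missing` is idempotent, and `override_all` followed by
#'   `fill_missing` equals `override_all` alone.
#' @export
annotate_track <- function(x, provider,
                           policy = c("fill_missing", "override_all")) {
  stopifnot(inherits(x, "track"), is.function(provider))
  policy <- match.arg(policy)
  p <- x$points
  looked <- provider(p$lat, p$lon)
  if (length(looked) != nrow(p))
    stop("provider returned ", length(looked), " values for ", nrow(p), " points")
  target <- if (policy == "fill_missing") is.na(p$ele) else rep(TRUE, nrow(p))
  fill <- target & !is.na(looked)
  p$ele[fill] <- looked[fill]
  n_uncovered <- sum(target & is.na(looked))
  if (n_uncovered)
    message(n_uncovered, " point(s) not covered by the provider retain prior elevation")
  still_missing <- which(is.na(p$ele))
  if (length(still_missing))
    stop("elevation still absent after annotation at point(s) ",
         paste(utils::head(still_missing, 10L), collapse = ", "),
         if (length(still_missing) > 10L) ", ..." else "")
  out <- x
  out$points <- p
  out
}
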