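# Minimal in-memory regular lat/lon raster, cell-centre registered, plus
# plain-text (ESRI ASCII grid) serialisation and the zonal statistic used
# by the range module. Rows are indexed from south (row 1 = southernmost
# cell), columns from west.

#' Construct a regular lat/lon raster
#'
#' @param lat,lon Cell-centre coordinates, strictly increasing, evenly
#'   spaced (same spacing in both axes is not required).
#' @param values Numeric or integer matrix with `length(lat)` rows and
#'   `length(lon)` columns; `values[i, j]` is the cell centred at
#'   `(lat[i], lon[j])`.
#' @param varname Name of the stored variable (e.g. `"snow_pct"`).
#' @param levels Optional character vector naming integer classes for
#'   categorical rasters.
#' @return An object of class `fox_raster`.
#' @export
fox_raster <- function(lat, lon, values, varname = "value", levels = NULL) {
  stopifnot(is.numeric(lat), is.numeric(lon), is.matrix(values),
            nrow(values) == length(lat), ncol(values) == length(lon))
  if (length(lat) > 1 && any(diff(lat) <= 0)) stop("lat must be increasing")
  if (length(lon) > 1 && any(diff(lon) <= 0)) stop("lon must be increasing")
  res_lat <- if (length(lat) > 1) diff(lat)[1] else 1
  res_lon <- if (length(lon) > 1) diff(lon)[1] else 1
  if (length(lat) > 2 && max(abs(diff(lat) - res_lat)) > 1e-9)
    stop("lat spacing must be regular")
  if (length(lon) > 2 && max(abs(diff(lon) - res_lon)) > 1e-9)
    stop("lon spacing must be regular")
  structure(list(lat = lat, lon = lon, values = values, varname = varname,
                 levels = levels, res_lat = res_lat, res_lon = res_lon),
            class = "fox_raster")
}

#' @export
print.fox_raster <- function(x, ...) {
  cat("fox_raster:", x$varname, "\n")
  cat(sprintf("  %d rows (lat %.3f..%.3f) x %d cols (lon %.3f..%.3f)\n",
              length(x$lat), min(x$lat), max(x$lat),
              length(x$lon), min(x$lon), max(x$lon)))
  if (!is.null(x$levels)) cat("  classes:", paste(x$levels, collapse = ", "), "\n")
  else cat("  range:", paste(format(range(x$values), digits = 4), collapse = " .. "), "\n")
  invisible(x)
}

#' Locate the cell containing each position
#'
#' Cells cover half-open intervals around their centres; a position that
#' falls exactly on a shared edge is assigned to the cell with the smaller
#' row index, then the smaller column index. Positions outside the raster
#' extent get NA indices.
#'
#' @param r A [fox_raster()].
#' @param lat,lon Position coordinates (vectors of equal length).
#' @return A data.frame with columns `row`, `col` (NA when outside).
#' @export
raster_cell_index <- function(r, lat, lon) {
  stopifnot(inherits(r, "fox_raster"), length(lat) == length(lon))
  lo_lat <- r$lat[1] - r$res_lat / 2
  lo_lon <- r$lon[1] - r$res_lon / 2
  # ceiling() puts a coordinate exactly on an internal edge into the
  # lower-index cell; the southern/western outer edge maps to index 0 and
  # is clamped into cell 1.
  row <- ceiling((lat - lo_lat) / r$res_lat)
  col <- ceiling((lon - lo_lon) / r$res_lon)
  row[row == 0 & lat >= lo_lat - 1e-12] <- 1L
  col[col == 0 & lon >= lo_lon - 1e-12] <- 1L
  bad <- row < 1 | row > length(r$lat) | col < 1 | col > length(r$lon)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Raster value at positions
#'
#' Containing-cell (no interpolation) lookup.
#'
#' @inheritParams raster_cell_index
#' @return Vector of cell values (NA outside the extent).
#' @export
raster_lookup <- function(r, lat, lon) {
  idx <- raster_cell_index(r, lat, lon)
  out <- rep(NA_real_, nrow(idx))
  ok <- !is.na(idx$row)
  out[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
  if (!is.null(r$levels)) {
    lv <- rep(NA_character_, length(out))
    lv[ok] <- r$levels[out[ok]]
    return(lv)
  }
  out
}

#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd ray casting with an explicit on-segment check so points lying
#' exactly on an edge or vertex count as inside.
#'
#' @param px,py Point coordinates.
#' @param vx,vy Polygon vertex coordinates (ring; closure optional).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, vx, vy) {
  stopifnot(length(px) == length(py), length(vx) == length(vy), length(vx) >= 3)
  # drop an explicit closing vertex
  n <- length(vx)
  if (vx[1] == vx[n] && vy[1] == vy[n]) { vx <- vx[-n]; vy <- vy[-n]; n <- n - 1 }
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  tol <- 1e-12
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # on-segment: zero cross product and within the bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    on <- abs(cross) <= tol * max(1, sqrt(seg_len2)) &
      px >= pmin(x1, x2) - tol & px <= pmax(x1, x2) + tol &
      py >= pmin(y1, y2) - tol & py <= pmax(y1, y2) + tol
    onedge <- onedge | on
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onedge
}

#' Mean raster value inside a polygon
#'
#' Unweighted mean over cells whose centres fall inside (or on the
#' boundary of) the polygon — the usual zonal statistic for coarse
#' environmental rasters.
#'
#' @param r A numeric [fox_raster()].
#' @param polygon A two-column matrix or data.frame of `(lon, lat)`
#'   vertices.
#' @return Scalar mean of the covered cell values.
#' @export
extract_mean_snow <- function(r, polygon) {
  stopifnot(inherits(r, "fox_raster"))
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3)
    stop("polygon must have >= 3 (lon, lat) vertices")
  cx <- rep(r$lon, each = length(r$lat))
  cy <- rep(r$lat, times = length(r$lon))
  keep <- point_in_polygon(cx, cy, polygon[, 1], polygon[, 2])
  if (!any(keep))
    stop("no cell centres fall inside the polygon; use a finer grid")
  mean(as.numeric(r$values)[keep])
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text serialisation (NCOLS/NROWS/XLLCORNER/YLLCORNER/CELLSIZE
#' header, rows north to south), readable by standard GIS software.
#' Requires equal lat and lon spacing.
#'
#' @param r A [fox_raster()].
#' @param path File path.
#' @param varname,levels Metadata to attach on read (see [fox_raster()]).
#' @return `write_raster_asc()` returns `path` invisibly;
#'   `read_raster_asc()` returns a `fox_raster`.
#' @export
write_raster_asc <- function(r, path) {
  stopifnot(inherits(r, "fox_raster"))
  if (abs(r$res_lat - r$res_lon) > 1e-9)
    stop("ASCII grid requires square cells")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", length(r$lon)),
    sprintf("NROWS %d", length(r$lat)),
    sprintf("XLLCORNER %.10g", r$lon[1] - r$res_lon / 2),
    sprintf("YLLCORNER %.10g", r$lat[1] - r$res_lat / 2),
    sprintf("CELLSIZE %.10g", r$res_lat),
    "NODATA_VALUE -9999"), con)
  m <- r$values[rev(seq_along(r$lat)), , drop = FALSE]  # north first
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_asc
#' @export
read_raster_asc <- function(path, varname = "value", levels = NULL) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), toupper(kv[, 1]))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  if (nrow(m) != h["NROWS"] || ncol(m) != h["NCOLS"])
    stop("ASCII grid dimensions do not match header")
  cs <- h["CELLSIZE"]
  lat <- h["YLLCORNER"] + cs / 2 + cs * (seq_len(nrow(m)) - 1)
  lon <- h["XLLCORNER"] + cs / 2 + cs * (seq_len(ncol(m)) - 1)
  fox_raster(lat, lon, m[rev(seq_len(nrow(m))), , drop = FALSE],
             varname = varname, levels = levels)
}
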