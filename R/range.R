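# Monthly 95% minimum convex polygons of the pooled wintering population,
# snow extraction per footprint, the two counterfactual residency
# scenarios, and the displacement-vs-snow regression.

.month_of <- function(date) as.integer(format(as.Date(date), "%m"))

#' Monthly minimum convex polygon
#'
#' Pools the daily positions of all birds in one calendar month, ranks
#' them by great-circle distance to their centroid (the arithmetic mean
#' position), retains the `ceiling(level * n)` nearest (ties keep the
#' earlier record), and takes the convex hull of the retained points in
#' the lon/lat plane — the standard percent-MCP range estimator.
#'
#' @param daily Daily-track data.frame (`date`, `lat`, `lon`).
#' @param month Calendar month 1-12.
#' @param level Retention level in (0, 1]; default 0.95.
#' @return An object of class `monthly_range`: list with `month`,
#'   `points_used`, `retained`, `hull` (closed ring, columns `lon`,
#'   `lat`), `centroid`, `n`, `area_deg2` (planar shoelace area of the
#'   hull), `degenerate` flag.
#' @export
monthly_mcp <- function(daily, month, level = 0.95) {
  stopifnot(level > 0, level <= 1)
  pts <- daily[.month_of(daily$date) == month, , drop = FALSE]
  if (nrow(pts) < 5) stop("fewer than 5 positions in month ", month)
  centroid <- c(lat = mean(pts$lat), lon = mean(pts$lon))
  d <- haversine_km(pts$lat, pts$lon, centroid["lat"], centroid["lon"])
  k <- ceiling(level * nrow(pts))
  ord <- order(d, seq_len(nrow(pts)))  # ties keep the earlier record
  retained <- pts[sort(ord[seq_len(k)]), , drop = FALSE]
  h <- grDevices::chull(retained$lon, retained$lat)
  hull <- cbind(lon = retained$lon[h], lat = retained$lat[h])
  degenerate <- nrow(hull) < 3
  hull <- rbind(hull, hull[1, , drop = FALSE])  # close the ring
  structure(list(month = month, points_used = pts, retained = retained,
                 hull = hull, centroid = centroid, n = nrow(pts),
                 area_deg2 = polygon_area(hull[, "lon"], hull[, "lat"]),
                 level = level, degenerate = degenerate),
            class = "monthly_range")
}

#' @export
print.monthly_range <- function(x, ...) {
  cat(sprintf("%d%% MCP, month %d: %d of %d positions retained, %d hull vertices, area %.2f deg^2\n",
              round(100 * x$level), x$month, nrow(x$retained), x$n,
              nrow(x$hull) - 1, x$area_deg2))
  invisible(x)
}

#' Planar polygon area (shoelace formula)
#'
#' @param x,y Vertex coordinates (ring; closure optional).
#' @return Absolute area in squared coordinate units.
#' @export
polygon_area <- function(x, y) {
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

.winter_months <- c(10, 11, 12, 1, 2, 3, 4)

# MCP of positions pooled over several calendar months.
.pooled_mcp <- function(daily, months, level = 0.95) {
  sel <- .month_of(daily$date) %in% months
  sub <- daily[sel, , drop = FALSE]
  sub$date <- as.Date("2000-01-15")  # collapse to a single pseudo-month
  monthly_mcp(sub, 1, level)
}

#' Realized and counterfactual snow-exposure series
#'
#' For each winter month, the realized series is the mean fractional snow
#' cover of that month's raster inside that month's 95% MCP. The
#' stay-north counterfactual evaluates every month's raster inside the
#' fixed MCP of the pooled October + April positions (the footprint where
#' the birds arrive and depart); the direct-southwest counterfactual uses
#' the pooled January + February footprint (the far south-west of the
#' winter range).
#'
#' @param daily Daily-track data.frame.
#' @param snow Named list of monthly snow [fox_raster()] layers as from
#'   [simulate_snow()] (one layer per winter month, October to April).
#' @param level MCP level, default 0.95.
#' @return A data.frame with columns `month`, `realized`, `stay_north`,
#'   `direct_southwest` (percent), with the three footprint polygons
#'   attached as attributes.
#' @export
scenario_series <- function(daily, snow, level = 0.95) {
  months <- attr(snow, "months")
  if (is.null(months)) months <- .winter_months[seq_along(snow)]
  mcps <- lapply(months, function(m) monthly_mcp(daily, m, level))
  north <- .pooled_mcp(daily, c(10, 4), level)
  sw <- .pooled_mcp(daily, c(1, 2), level)
  out <- data.frame(month = months,
                    realized = NA_real_, stay_north = NA_real_,
                    direct_southwest = NA_real_)
  for (k in seq_along(months)) {
    out$realized[k] <- extract_mean_snow(snow[[k]], mcps[[k]]$hull)
    out$stay_north[k] <- extract_mean_snow(snow[[k]], north$hull)
    out$direct_southwest[k] <- extract_mean_snow(snow[[k]], sw$hull)
  }
  attr(out, "mcps") <- mcps
  attr(out, "footprints") <- list(stay_north = north, direct_southwest = sw)
  out
}

#' Contrasts between realized and counterfactual snow exposure
#'
#' Per-month differences stay_north - realized and realized -
#' direct_southwest, the month of peak contrast, and season means.
#'
#' @param series Data.frame from [scenario_series()] (columns `month`,
#'   `realized`, `stay_north`, `direct_southwest`).
#' @return A list with `per_month` (data.frame), `peak_stay_north`
#'   (month and value of the largest stay_north - realized difference),
#'   `peak_direct_southwest`, and `season_means`.
#' @export
scenario_contrast <- function(series) {
  pm <- data.frame(month = series$month,
                   stay_north_minus_realized =
                     series$stay_north - series$realized,
                   realized_minus_direct_southwest =
                     series$realized - series$direct_southwest)
  i1 <- which.max(pm$stay_north_minus_realized)
  i2 <- which.max(pm$realized_minus_direct_southwest)
  list(per_month = pm,
       peak_stay_north = c(month = pm$month[i1],
                           value = pm$stay_north_minus_realized[i1]),
       peak_direct_southwest = c(month = pm$month[i2],
                                 value = pm$realized_minus_direct_southwest[i2]),
       season_means = c(realized = mean(series$realized),
                        stay_north = mean(series$stay_north),
                        direct_southwest = mean(series$direct_southwest)))
}

#' Month-to-month range shifts and snow covariates
#'
#' For each pair of consecutive winter months: the great-circle distance
#' between the centroids of the two monthly MCPs, the mean snow cover at
#' the first month's footprint, and the difference in snow cover between
#' the two footprints (each evaluated on its own month's raster).
#'
#' @inheritParams scenario_series
#' @return Data.frame with `from_month`, `to_month`,
#'   `centroid_distance_km`, `snow_at_first`, `snow_difference`.
#' @export
range_shifts <- function(daily, snow, level = 0.95) {
  months <- attr(snow, "months")
  if (is.null(months)) months <- .winter_months[seq_along(snow)]
  mcps <- lapply(months, function(m) monthly_mcp(daily, m, level))
  sn <- vapply(seq_along(months), function(k)
    extract_mean_snow(snow[[k]], mcps[[k]]$hull), numeric(1))
  n <- length(months) - 1
  out <- data.frame(from_month = months[seq_len(n)],
                    to_month = months[seq_len(n) + 1],
                    centroid_distance_km = NA_real_,
                    snow_at_first = sn[seq_len(n)],
                    snow_difference = diff(sn))
  for (k in seq_len(n)) {
    c0 <- mcps[[k]]$centroid; c1 <- mcps[[k + 1]]$centroid
    out$centroid_distance_km[k] <- haversine_km(c0["lat"], c0["lon"],
                                                c1["lat"], c1["lon"])
  }
  out
}

#' Regression of range displacement on snow cover
#'
#' Ordinary least squares of the consecutive-MCP centroid distance on the
#' snow cover at the first footprint and the snow-cover difference, the
#' test of whether snow conditions drive the month-to-month displacement.
#'
#' @param shifts Data.frame from [range_shifts()] (>= 4 rows), or rows
#'   pooled across seasons/replicates.
#' @return The fitted [stats::lm()] object; its coefficient table carries
#'   t-based p-values via `summary()`.
#' @export
shift_vs_snow_regression <- function(shifts) {
  if (nrow(shifts) < 4) stop("need at least 4 month-pairs")
  X <- cbind(1, shifts$snow_at_first, shifts$snow_difference)
  if (qr(X)$rank < 3) stop("rank-deficient design: regressors are collinear")
  stats::lm(centroid_distance_km ~ snow_at_first + snow_difference,
            data = shifts)
}
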