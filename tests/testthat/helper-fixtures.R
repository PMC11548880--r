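# Shared fixture builders. Everything is generated in code; no files.

# Daily track whose latitude is exactly piecewise linear in the
# consecutive day axis, with knots at `knots` (consecutive DOY) and
# per-segment latitude slopes `slopes` (length(knots) + 1). Longitude
# follows an analogous piecewise-linear path.
linear_track <- function(bird_id = "B1", doys = 182:546,
                         knots = c(271, 285, 401, 482, 500),
                         slopes = c(0, -0.9, -0.03, 0.08, 0.9, 0),
                         lon_slopes = c(0, -0.35, -0.11, 0.2, 0.1, 0),
                         lat0 = 68, lon0 = 58) {
  seg <- findInterval(doys, knots) + 1
  lat <- lat0 + cumsum(c(0, slopes[seg[-length(seg)]]))
  lon <- lon0 + cumsum(c(0, lon_slopes[seg[-length(seg)]]))
  data.frame(bird_id = bird_id, season_year = 2021L,
             date = as.Date("2021-01-01") + (doys - 1),
             doy = doys, lat = lat, lon = lon,
             stringsAsFactors = FALSE)
}

# Independent brute-force two-segment search used as the oracle for
# search_break(): plain lm() per side, exhaustive over candidates.
brute_force_break <- function(daily, window, fit_margin = c(30, 30)) {
  fit_margin <- rep_len(fit_margin, 2)
  sl <- daily[daily$doy >= window[1] - fit_margin[1] &
                daily$doy <= window[2] + fit_margin[2], ]
  best <- NULL
  for (b in seq(window[1], window[2])) {
    l <- sl[sl$doy < b, ]; r <- sl[sl$doy >= b, ]
    n <- nrow(l) + nrow(r)
    if (nrow(l) < 2 || nrow(r) < 2 || n <= 4) next
    if (length(unique(l$doy)) < 2 || length(unique(r$doy)) < 2) next
    rss <- sum(resid(lm(lat ~ doy, data = l))^2) +
      sum(resid(lm(lat ~ doy, data = r))^2)
    rse <- sqrt(rss / (n - 4))
    if (is.null(best) || rse < best$rse - 1e-9)
      best <- list(break_doy = b, rse = rse, rss = rss)
  }
  best
}

# Spherical law-of-cosines distance, independent of the haversine route.
sloc_km <- function(lat1, lon1, lat2, lon2, R = 6378.137) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  R * acos(pmin(1, pmax(-1, sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl))))
}

# Closed-form initial bearing from the standard atan2 formula.
atan2_bearing <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  th <- atan2(sin(dl) * cos(p2),
              cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl))
  (th * 180 / pi + 360) %% 360
}

# Small track-point table for io tests.
toy_points <- function() {
  data.frame(bird_id = c("A", "A", "A", "B"),
             timestamp = as.POSIXct(c("2021-10-01 06:00:00",
                                      "2021-10-01 18:00:00",
                                      "2021-10-02 12:00:00",
                                      "2021-10-01 06:00:00"), tz = "UTC"),
             lat = c(50, 52, 51, 60), lon = c(40, 42, 41, 30),
             stringsAsFactors = FALSE)
}
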