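make_daily <- function(lat, lon, month = 1, bird = "A") {
  n <- max(length(lat), length(lon))
  data.frame(bird_id = bird, season_year = 2021L,
             date = as.Date(sprintf("2022-%02d-01", month)) +
               seq_len(n) %% 27,
             doy = seq_len(n), lat = rep_len(lat, n), lon = rep_len(lon, n))
}

test_that("95% MCP retains the right count and hull", {
  set.seed(51)
  d <- make_daily(50 + rnorm(20, 0, 0.5), 40 + rnorm(20, 0, 0.5))
  r <- monthly_mcp(d, 1, level = 0.95)
  expect_equal(nrow(r$retained), 19)  # ceil(0.95 * 20)
  # hull vertices are retained points and hull contains every retained point
  expect_true(all(r$hull[, "lon"] %in% r$retained$lon))
  inside <- point_in_polygon(r$retained$lon, r$retained$lat,
                             r$hull[, "lon"], r$hull[, "lat"])
  expect_true(all(inside))

  # square plus centre at level 1: hull is the square
  sq <- make_daily(c(0, 0, 2, 2, 1), c(0, 2, 0, 2, 1))
  rs <- monthly_mcp(sq, 1, level = 1)
  expect_equal(nrow(rs$retained), 5)
  expect_equal(rs$area_deg2, 4)
  expect_equal(nrow(rs$hull) - 1, 4)
  expect_error(monthly_mcp(make_daily(1:3, 1:3), 1), "fewer than 5")
})

test_that("hull area equals an independent triangle-fan oracle", {
  set.seed(52)
  for (i in 1:5) {
    d <- make_daily(50 + rnorm(40, 0, 1), 40 + rnorm(40, 0, 2))
    r <- monthly_mcp(d, 1)
    h <- r$hull[-nrow(r$hull), ]
    cx <- mean(h[, "lon"]); cy <- mean(h[, "lat"])
    fan <- 0
    for (k in seq_len(nrow(h))) {
      k2 <- if (k == nrow(h)) 1 else k + 1
      fan <- fan + abs((h[k, "lon"] - cx) * (h[k2, "lat"] - cy) -
                         (h[k2, "lon"] - cx) * (h[k, "lat"] - cy)) / 2
    }
    expect_equal(r$area_deg2, unname(fan), tolerance = 1e-10)
  }
})

test_that("shrinking the MCP level never enlarges the hull", {
  set.seed(53)
  d <- make_daily(50 + rnorm(60, 0, 1), 40 + rnorm(60, 0, 2))
  areas <- vapply(seq(0.5, 1, by = 0.05), function(lv)
    monthly_mcp(d, 1, level = lv)$area_deg2, numeric(1))
  expect_true(all(diff(areas) >= -1e-12))
})

test_that("point-in-polygon is boundary inclusive and matches mgcv", {
  sqx <- c(0, 2, 2, 0); sqy <- c(0, 0, 2, 2)
  expect_true(all(point_in_polygon(c(1, 0, 2, 1, 0), c(1, 0, 1, 2, 1),
                                   sqx, sqy)))
  expect_false(any(point_in_polygon(c(-0.1, 3, 1), c(1, 1, 2.5), sqx, sqy)))

  skip_if_not_installed("mgcv")
  set.seed(54)
  for (i in 1:3) {
    pts <- cbind(runif(12), runif(12))
    h <- grDevices::chull(pts)
    poly <- pts[h, ]
    qx <- runif(300); qy <- runif(300)
    # random continuous points are almost surely off the boundary, where
    # the two implementations must agree exactly
    ours <- point_in_polygon(qx, qy, poly[, 1], poly[, 2])
    theirs <- as.logical(mgcv::in.out(rbind(poly, poly[1, ]),
                                      cbind(qx, qy)))
    expect_equal(ours, theirs)
  }
})

test_that("zonal snow means respect limits and counting oracles", {
  r <- fox_raster(lat = seq(0.5, 9.5, 1), lon = seq(0.5, 9.5, 1),
                  values = matrix(7, 10, 10), varname = "snow_pct")
  poly <- cbind(lon = c(2, 8, 8, 2), lat = c(2, 2, 8, 8))
  expect_equal(extract_mean_snow(r, poly), 7)

  # half-plane 0/100 split evenly through the polygon
  v <- matrix(0, 10, 10); v[6:10, ] <- 100  # north half snow-covered
  r2 <- fox_raster(seq(0.5, 9.5, 1), seq(0.5, 9.5, 1), v)
  got <- extract_mean_snow(r2, poly)
  # rows 2.5..7.5 inside: three bare, three covered (boundary rows included)
  covered <- sum(r2$lat >= 2 & r2$lat <= 8 & r2$lat > 5)
  total <- sum(r2$lat >= 2 & r2$lat <= 8)
  expect_equal(got, 100 * covered / total)
  expect_gte(got, min(v)); expect_lte(got, max(v))

  south <- cbind(lon = c(2, 8, 8, 2), lat = c(0.2, 0.2, 4, 4))
  expect_equal(extract_mean_snow(r2, south), 0)
  tiny <- cbind(lon = c(2.1, 2.2, 2.2, 2.1), lat = c(2.1, 2.1, 2.2, 2.2))
  expect_error(extract_mean_snow(r2, tiny), "finer grid")
})

test_that("stationary birds make all three scenario series coincide", {
  set.seed(55)
  base_lat <- 52 + rnorm(30, 0, 0.8); base_lon <- 40 + rnorm(30, 0, 0.8)
  daily <- do.call(rbind, lapply(c(10:12, 1:4), function(m) {
    yr <- if (m >= 7) 2021 else 2022
    data.frame(bird_id = sprintf("B%02d", 1:30), season_year = 2021L,
               date = as.Date(sprintf("%d-%02d-15", yr, m)),
               doy = 1, lat = base_lat, lon = base_lon)
  }))
  cfg <- sim_config(seed = 1)
  snow <- simulate_snow(cfg)
  ser <- scenario_series(daily, snow)
  expect_equal(ser$realized, ser$stay_north, tolerance = 1e-9)
  expect_equal(ser$realized, ser$direct_southwest, tolerance = 1e-9)
})

test_that("a resident-in-the-southwest population sees realized = direct-SW", {
  # birds rush to the south-west right after fall and stay: slow drift off
  cfg <- sim_config(n_birds = 6,
                    phase_speeds = c(Qf = 107, S1 = 90, S2 = 0.1, Qs = 100),
                    phase_start_doys = c(fall_start = 271, fall_end = 285,
                                         winter_turn = 300,
                                         spring_start = 482,
                                         spring_end = 500),
                    phase_start_sd = c(fall_start = 3, fall_end = 3,
                                       winter_turn = 2, spring_start = 3,
                                       spring_end = 3),
                    seed = 19)
  daily <- preprocess_tracks(simulate_tracks(cfg))
  snow <- simulate_snow(cfg)
  ser <- scenario_series(daily, snow)
  mid <- ser$month %in% c(12, 1, 2, 3)
  expect_lt(max(abs(ser$realized[mid] - ser$direct_southwest[mid])), 6)
})

test_that("winter footprint ordering: north snowier than south mid-winter", {
  cfg <- sim_config(seed = 1)
  daily <- preprocess_tracks(simulate_tracks(cfg))
  snow <- simulate_snow(cfg)
  ser <- scenario_series(daily, snow)
  jf <- ser$month %in% c(1, 2)
  expect_true(all(ser$stay_north[jf] > ser$realized[jf]))
  expect_true(all(ser$stay_north[jf] > ser$direct_southwest[jf]))
  # over the season the realized strategy beats staying north and loses
  # to the direct-southwest one
  expect_gt(mean(ser$stay_north), mean(ser$realized))
  expect_gt(mean(ser$realized), mean(ser$direct_southwest))
})

test_that("scenario contrasts reproduce the published worked examples", {
  ser <- data.frame(month = c(1, 2), realized = c(60, 85.1),
                    stay_north = c(70, 99.5), direct_southwest = c(50, 59.4))
  ct <- scenario_contrast(ser)
  expect_equal(ct$per_month$stay_north_minus_realized[2], 14.4)
  expect_equal(unname(ct$peak_stay_north["value"]), 14.4)
  ser2 <- data.frame(month = 1, realized = 57.3, stay_north = 60,
                     direct_southwest = 31.6)
  expect_equal(scenario_contrast(ser2)$per_month$realized_minus_direct_southwest,
               25.7)
  same <- data.frame(month = 1:3, realized = 5, stay_north = 5,
                     direct_southwest = 5)
  expect_true(all(scenario_contrast(same)$per_month[, -1] == 0))
})

test_that("displacement regression matches the normal-equations oracle", {
  set.seed(56)
  sh <- data.frame(from_month = 1:8, to_month = 2:9,
                   snow_at_first = runif(8, 0, 100),
                   snow_difference = runif(8, -20, 20))
  sh$centroid_distance_km <- 2 * sh$snow_at_first
  fit <- shift_vs_snow_regression(sh)
  expect_equal(unname(coef(fit)["snow_at_first"]), 2, tolerance = 1e-9)
  expect_lt(suppressWarnings(summary(fit))$coefficients["snow_at_first", 4],
            1e-9)

  sh$centroid_distance_km <- 100 + 3 * sh$snow_at_first -
    5 * sh$snow_difference + rnorm(8)
  fit2 <- shift_vs_snow_regression(sh)
  X <- cbind(1, sh$snow_at_first, sh$snow_difference)
  beta <- solve(crossprod(X), crossprod(X, sh$centroid_distance_km))
  expect_equal(unname(coef(fit2)), as.numeric(beta), tolerance = 1e-10)
  expect_error(shift_vs_snow_regression(sh[1:3, ]), "at least 4")
  sh$snow_difference <- sh$snow_at_first
  expect_error(shift_vs_snow_regression(sh), "rank")
})

test_that("range shifts pair consecutive months with their snow values", {
  cfg <- sim_config(n_birds = 10, seed = 20)
  daily <- preprocess_tracks(simulate_tracks(cfg))
  snow <- simulate_snow(cfg)
  sh <- range_shifts(daily, snow)
  expect_equal(nrow(sh), 6)
  expect_true(all(sh$centroid_distance_km >= 0))
  # internal consistency: first-footprint snow plus the difference is the
  # next month's first-footprint snow
  expect_equal(sh$snow_at_first[-1],
               (sh$snow_at_first + sh$snow_difference)[-6], tolerance = 1e-9)
  # month-to-month displacement exceeds zero during the drift
  expect_gt(mean(sh$centroid_distance_km), 50)
})
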