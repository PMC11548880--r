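test_that("config validation rejects impossible study systems", {
  expect_error(sim_config(n_birds = 0), "n_birds")
  expect_error(sim_config(phase_speeds = c(Qf = -1, S1 = 8, S2 = 17, Qs = 100)),
               "speeds")
  expect_error(sim_config(phase_directions = c(Qf = 360, S1 = 251, S2 = 57,
                                               Qs = 7)), "directions")
  expect_error(sim_config(position_noise_sd = -0.1), "noise")
  bad_bands <- list(breaks = c(40, 66, 57, 80),
                    weights = sim_config()$landcover_bands$weights)
  expect_error(sim_config(landcover_bands = bad_bands), "overlapping")
  sp <- sim_config()$snowline_params; sp$width <- 0
  expect_error(sim_config(snowline_params = sp), "width")
})

test_that("noiseless tracks step at the configured speed along each phase", {
  cfg <- sim_config(n_birds = 1, position_noise_sd = 0, dup_frac = 0,
                    phase_start_sd = c(fall_start = 0, fall_end = 0,
                                       winter_turn = 0, spring_start = 0,
                                       spring_end = 0),
                    quick_duration_sd = c(Qf = 0, Qs = 0),
                    breeding_spread = c(lat = 0, lon = 0), seed = 1)
  tr <- simulate_tracks(cfg)
  daily <- preprocess_tracks(tr)
  truth <- attr(tr, "truth")
  qf <- daily[daily$doy >= truth$fall_start & daily$doy <= truth$fall_end, ]
  steps <- haversine_km(qf$lat[-nrow(qf)], qf$lon[-nrow(qf)],
                        qf$lat[-1], qf$lon[-1])
  expect_lt(max(abs(steps - 107)), 0.1)
  # stationary during breeding
  br <- daily[daily$doy < truth$fall_start, ]
  expect_lt(max(haversine_km(br$lat[1], br$lon[1], br$lat, br$lon)), 1e-6)
})

test_that("default generator reproduces the configured fall speed", {
  cfg <- sim_config(seed = 8)
  tr <- simulate_tracks(cfg)
  daily <- preprocess_tracks(tr)
  truth <- attr(tr, "truth")
  per_bird <- vapply(seq_len(nrow(truth)), function(i) {
    g <- daily[daily$bird_id == truth$bird_id[i] &
                 daily$doy >= truth$fall_start[i] &
                 daily$doy <= truth$fall_end[i], ]
    haversine_km(g$lat[1], g$lon[1], g$lat[nrow(g)], g$lon[nrow(g)]) /
      (nrow(g) - 1)
  }, numeric(1))
  expect_lt(abs(mean(per_bird) - 107), 2 * sd(per_bird))
})

test_that("generator output is bit-identical under a fixed seed", {
  cfg <- sim_config(n_birds = 4, seed = 77)
  expect_identical(simulate_tracks(cfg), simulate_tracks(cfg))
  expect_identical(simulate_snow(cfg), simulate_snow(cfg))
  expect_identical(simulate_landcover(cfg), simulate_landcover(cfg))
})

test_that("drawn boundaries are ordered and sit inside their windows", {
  cfg <- sim_config(seed = 5)
  truth <- attr(simulate_tracks(cfg), "truth")
  b <- as.matrix(truth[, c("fall_start", "fall_end", "winter_turn",
                           "spring_start", "spring_end")])
  expect_true(all(t(apply(b, 1, diff)) > 0))
  w <- cfg$boundary_windows
  expect_true(all(b[, "fall_start"] >= w$fall_start[1] &
                    b[, "fall_start"] <= w$fall_start[2]))
  expect_true(all(b[, "spring_end"] >= w$spring_end[1] &
                    b[, "spring_end"] <= w$spring_end[2]))
  expect_equal(sum(truth$sex == "F"), 35)
  expect_equal(sum(truth$sex == "M"), 8)
})

test_that("snow field follows the logistic snowline with correct limits", {
  sp <- list(months = c(10, 11, 12, 1, 2, 3, 4),
             snowline_lat = c(60, 57, 54, 51, 50, 53, 58),
             tilt = 0, lon_ref = 49, width = 1e-9, noise_sd = 0)
  cfg <- sim_config(n_birds = 1, snowline_params = sp, seed = 2)
  snow <- simulate_snow(cfg)
  r <- snow[[1]]
  north <- r$values[r$lat > 60.5, ]
  south <- r$values[r$lat < 59.5, ]
  expect_true(all(north == 100))
  expect_true(all(south == 0))

  # logistic midpoint: cell exactly on the snowline gives 50
  sp$width <- 2
  sp$snowline_lat <- rep(60.25, 7)  # a cell-centre latitude of the grid
  cfg <- sim_config(n_birds = 1, snowline_params = sp, seed = 2)
  r <- simulate_snow(cfg)[[1]]
  expect_equal(unique(r$values[r$lat == 60.25, ]), 50)

  # monotone snowline advance implies monotone per-cell snow Oct -> Feb
  cfg <- sim_config(seed = 4)
  sp <- cfg$snowline_params; sp$noise_sd <- 0
  cfg$snowline_params <- sp
  snow <- simulate_snow(cfg)
  vals <- sapply(snow[1:5], function(r) r$values[30, 80])
  expect_true(all(diff(vals) >= 0))
})

test_that("land-cover bands mix classes with the configured weights", {
  lb <- list(breaks = c(40, 80),
             weights = rbind(all = c(forest = 1, grassland = 0, cropland = 0,
                                     shrubland = 0, urban = 0)))
  cfg <- sim_config(landcover_bands = lb, seed = 3)
  lc <- simulate_landcover(cfg)
  expect_true(all(lc$values == which(lc$levels == "forest")))

  cfg <- sim_config(seed = 3)
  lc <- simulate_landcover(cfg)
  taiga <- lc$values[lc$lat > 57 & lc$lat < 66, ]
  share <- mean(taiga == which(lc$levels == "forest"))
  n <- length(taiga)
  expect_lt(abs(share - 0.92), 3 * sqrt(0.92 * 0.08 / n))
})

test_that("duplicated-timestamp injection is removed by preprocessing", {
  cfg <- sim_config(n_birds = 3, seed = 9)
  tr <- simulate_tracks(cfg)
  key <- paste(tr$bird_id, tr$timestamp)
  expect_gt(sum(duplicated(key)), 0)
  clean <- dedupe_timestamps(tr)
  expect_equal(sum(duplicated(paste(clean$bird_id, clean$timestamp))), 0)
  expect_equal(nrow(clean), 3 * 365)
})
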