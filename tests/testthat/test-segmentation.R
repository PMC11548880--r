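test_that("simple and piecewise fits match least-squares oracles", {
  expect_equal(fit_simple(1:10, 2 + 3 * (1:10))$rss, 0, tolerance = 1e-12)
  expect_error(fit_simple(1:2, 1:2), "at least 3")
  expect_error(fit_simple(rep(5, 4), 1:4), "degenerate")

  set.seed(41)
  x <- sort(runif(30, 0, 100)); y <- 1 + 0.2 * x + rnorm(30)
  fs <- fit_simple(x, y)
  beta <- solve(crossprod(cbind(1, x)), crossprod(cbind(1, x), y))
  expect_equal(fs$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fs$slope, beta[2], tolerance = 1e-10)
  expect_equal(fs$rse, sqrt(fs$rss / 28), tolerance = 1e-12)

  # two exact segments: zero RSS at the true break
  doys <- 1:40
  lats <- c(5 + 0.1 * (1:20), 10 - 0.3 * (1:20))
  fp <- fit_piecewise(doys, lats, 21)
  expect_equal(fp$rss, 0, tolerance = 1e-18)
  # infeasible: break outside the data range
  expect_null(fit_piecewise(doys, lats, 100))
  expect_null(fit_piecewise(doys, lats, 2))

  # any candidate equals the sum of two independent OLS fits
  set.seed(42)
  y2 <- rnorm(40)
  for (b in c(10, 21, 35)) {
    fp <- fit_piecewise(doys, y2, b)
    oracle <- sum(resid(lm(y2[doys < b] ~ doys[doys < b]))^2) +
      sum(resid(lm(y2[doys >= b] ~ doys[doys >= b]))^2)
    expect_equal(fp$rss, oracle, tolerance = 1e-10)
  }
})

test_that("breakpoint search equals the exhaustive brute-force oracle", {
  set.seed(43)
  for (i in 1:5) {
    d <- linear_track()
    d$lat <- d$lat + rnorm(nrow(d), 0, 0.3)
    for (w in list(c(248, 278), c(278, 309))) {
      got <- search_break(d, w, fit_margin = c(30, 30))
      want <- brute_force_break(d, w, c(30, 30))
      expect_equal(got$break_doy, want$break_doy)
      expect_equal(got$rse_piecewise, want$rse, tolerance = 1e-10)
      # piecewise nests the single line: RSS can only go down
      expect_lte(got$rss_piecewise, got$rss_simple + 1e-10)
    }
  }
})

test_that("noiseless piecewise-linear series recovers breaks exactly", {
  d <- linear_track()  # exact knots at 271/285/401/482/500
  expect_equal(search_break(d, c(248, 278), c(30, 0))$break_doy, 271)
  expect_equal(search_break(d, c(278, 309), c(0, 30))$break_doy, 285)
  expect_equal(search_break(d, c(465, 495), c(30, 0))$break_doy, 482)
  expect_equal(search_break(d, c(495, 526), c(0, 30))$break_doy, 500)
  # F test strongly favours the piecewise model at a real break
  expect_lt(search_break(d, c(248, 278), c(30, 0))$p_value, 1e-6)
})

test_that("tied residual error resolves to the earliest candidate day", {
  # symmetric V: breaks at the vertex and one step later fit equally well
  d <- data.frame(bird_id = "B", season_year = 2021L, doy = 250:290,
                  lat = abs(250:290 - 270) * 0.5 + 10,
                  lon = 0, date = as.Date("2021-01-01") + 250:290 - 1)
  got <- search_break(d, c(260, 280), c(10, 10))
  expect_equal(got$break_doy, 270)
})

test_that("winter turn finds the latitude minimum with first-day ties", {
  d <- linear_track()
  expect_equal(winter_turn(d, 285, 482), 401)
  plateau <- d
  plateau$lat[plateau$doy %in% 399:403] <- min(d$lat)
  expect_equal(winter_turn(plateau, 285, 482), 399)
  expect_error(winter_turn(d, 600, 700), "no positions")
})

test_that("phase-bound estimation composes, degrades, and validates order", {
  d <- linear_track()
  est <- estimate_phase_bounds(d)
  expect_true(est$ok)
  expect_equal(unname(est$bounds),
               c(271, 285, 401, 482, 500))

  # track truncated before spring: partial result with explicit NAs
  part <- d[d$doy < 430, ]
  est2 <- estimate_phase_bounds(part)
  expect_true(is.na(est2$bounds["spring_start"]))
  expect_true(is.na(est2$bounds["spring_end"]))
  expect_false(is.na(est2$bounds["fall_start"]))
  expect_match(est2$fits$spring_start$error, "window")
})

test_that("the fitted model recovers generator truth on noiseless tracks", {
  cfg <- sim_config(n_birds = 3, position_noise_sd = 0, dup_frac = 0,
                    seed = 14)
  tr <- simulate_tracks(cfg)
  daily <- preprocess_tracks(tr)
  fit <- fit_foxtrot(daily)
  truth <- attr(tr, "truth")
  est <- coef(fit)
  mig <- c("fall_start", "fall_end", "spring_start", "spring_end")
  # the knot day lies on both segments, so estimates match to +-1 day
  expect_lte(max(abs(est[, mig] - as.matrix(truth[, mig]))), 1)
  expect_equal(est[, "winter_turn"], unname(truth$winter_turn),
               ignore_attr = TRUE)
  expect_equal(length(fit$failed), 0)
  # piecewise-linear predictions track the latitudes closely
  expect_lt(stats::median(abs(residuals(fit)), na.rm = TRUE), 0.2)
})

test_that("noisy default simulations recover the migration dates", {
  cfg <- sim_config(n_birds = 15, seed = 15)
  tr <- simulate_tracks(cfg)
  daily <- preprocess_tracks(tr)
  fit <- fit_foxtrot(daily)
  truth <- attr(tr, "truth")
  est <- coef(fit)
  mig <- c("fall_start", "fall_end", "spring_start", "spring_end")
  err <- abs(est[, mig] - as.matrix(truth[, mig]))
  expect_gte(mean(err <= 2), 0.9)
  # winter turn scatters more (shallow slope vs noise); freeze observed scale
  expect_lte(stats::median(abs(est[, "winter_turn"] - truth$winter_turn)), 6)
  s <- summary(fit)
  expect_gte(s$frac_p_lt_001, 0.95)
  expect_lt(abs(s$boundaries$mean_doy[1] - mean(truth$fall_start)), 2)
})
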