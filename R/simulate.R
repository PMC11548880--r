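# Synthetic study system: multi-bird annual GPS tracks with four movement
# phases (quick fall, slow south-westward drift, slow north-eastward
# return, quick spring), monthly fractional snow-cover rasters with a
# snowline advancing SW and retreating NE, and a latitudinally zoned
# land-cover raster. Everything is seeded and bit-reproducible.

#' Configuration of the synthetic study system
#'
#' Defaults follow the published movement parameters of a satellite-tracked
#' Rough-legged buzzard population: 43 birds (35 females, 8 males), phase
#' travel speeds of 107 (quick fall), 8 (slow part 1), 17 (slow part 2) and
#' 100 (quick spring) km/day, phase bearings 198, 251, 57 and 7 degrees,
#' and phase boundary days (consecutive day-of-year axis starting 1 Jan of
#' the season's first calendar year) centred on 271, 285, 401, 482 and 500
#' with between-bird standard deviations 11, 11, 40, 7 and 8 days.
#' Because the published between-bird spread of the migration durations
#' (14 +- 4 days in fall, 18 +- 4 in spring) is much tighter than that of
#' the boundary days, each bird's quick-phase end day is drawn as start
#' day plus a duration draw rather than independently. Draws are rejected
#' until all four migration dates fall inside their search windows (and
#' the mid-winter turn inside the winter), so every simulated bird has a
#' well-posed four-phase season that the breakpoint search can recover.
#'
#' @param n_birds Number of birds (>= 1).
#' @param frac_female Proportion of females; the female count is
#'   `round(frac_female * n_birds)`.
#' @param phase_speeds Named numeric, km/day for phases `Qf`, `S1`, `S2`, `Qs`.
#' @param phase_directions Named numeric, degrees clockwise from north in
#'   `[0, 360)` for the four phases.
#' @param phase_start_doys Named numeric, mean consecutive DOY of
#'   `fall_start`, `fall_end`, `winter_turn`, `spring_start`, `spring_end`.
#' @param phase_start_sd Named numeric, between-bird sd (days) of each
#'   boundary (`fall_end` and `spring_end` sds are induced by the
#'   duration draws and ignored here).
#' @param quick_durations,quick_duration_sd Mean and sd (days) of the
#'   quick fall (`Qf`) and quick spring (`Qs`) migration durations.
#' @param boundary_windows List of `c(lo, hi)` consecutive-DOY truncation
#'   windows for the four migration boundaries (defaults are the
#'   piecewise-search windows of [migration_windows()]).
#' @param position_noise_sd Observation noise sd, degrees, applied
#'   independently to daily latitude and longitude.
#' @param breeding_origin,breeding_spread Mean and sd of the per-bird
#'   Arctic breeding location, `c(lat, lon)` degrees.
#' @param snowline_params List with `months` (calendar months Oct..Apr),
#'   `snowline_lat` (latitude of the 50% snow line at the reference
#'   meridian per month, decreasing then increasing), `tilt` (degrees of
#'   latitude the snowline drops per degree of longitude west of
#'   `lon_ref`, making the line advance towards the south-west), `lon_ref`
#'   (reference meridian, degrees E), `width` (logistic transition width,
#'   degrees > 0) and `noise_sd` (cell noise sd, percent).
#' @param landcover_bands List with `breaks` (increasing latitude
#'   breakpoints bounding the bands) and `weights` (one row per band,
#'   columns `forest`, `grassland`, `cropland`, `shrubland`, `urban`,
#'   rows summing to 1).
#' @param grid List with `lat_range`, `lon_range`, `res` (degrees) of the
#'   raster grid shared by snow and land cover.
#' @param dup_frac Fraction of track rows duplicated verbatim to exercise
#'   timestamp de-duplication (default 1%).
#' @param season_start_year Calendar year in which the simulated season
#'   begins on 1 July.
#' @param seed Integer master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_birds = 43,
                       frac_female = 35 / 43,
                       phase_speeds = c(Qf = 107, S1 = 8, S2 = 17, Qs = 100),
                       phase_directions = c(Qf = 198, S1 = 251, S2 = 57, Qs = 7),
                       phase_start_doys = c(fall_start = 271, fall_end = 285,
                                            winter_turn = 401,
                                            spring_start = 482,
                                            spring_end = 500),
                       phase_start_sd = c(fall_start = 11, fall_end = 11,
                                          winter_turn = 40, spring_start = 7,
                                          spring_end = 8),
                       quick_durations = c(Qf = 14, Qs = 18),
                       quick_duration_sd = c(Qf = 4, Qs = 4),
                       boundary_windows = list(fall_start = c(248, 278),
                                               fall_end = c(278, 309),
                                               spring_start = c(465, 495),
                                               spring_end = c(495, 526)),
                       position_noise_sd = 0.3,
                       breeding_origin = c(lat = 68.5, lon = 58),
                       breeding_spread = c(lat = 0.7, lon = 6),
                       snowline_params = list(
                         months = c(10, 11, 12, 1, 2, 3, 4),
                         snowline_lat = c(68.5, 55.5, 50.5, 47, 46, 48.5, 55),
                         tilt = 0.25, lon_ref = 49,
                         width = 1, noise_sd = 3),
                       landcover_bands = list(
                         breaks = c(40, 57, 66, 86),
                         weights = rbind(
                           wooded_fields = c(forest = 0.05, grassland = 0.63,
                                             cropland = 0.28, shrubland = 0.02,
                                             urban = 0.02),
                           taiga = c(forest = 0.92, grassland = 0.04,
                                     cropland = 0.00, shrubland = 0.04,
                                     urban = 0.00),
                           tundra = c(forest = 0.00, grassland = 0.40,
                                      cropland = 0.00, shrubland = 0.60,
                                      urban = 0.00))),
                       grid = list(lat_range = c(40, 86),
                                   lon_range = c(10, 100), res = 0.5),
                       dup_frac = 0.01,
                       season_start_year = 2021,
                       seed = 1) {
  cfg <- list(n_birds = n_birds, frac_female = frac_female,
              phase_speeds = phase_speeds,
              phase_directions = phase_directions,
              phase_start_doys = phase_start_doys,
              phase_start_sd = phase_start_sd,
              quick_durations = quick_durations,
              quick_duration_sd = quick_duration_sd,
              boundary_windows = boundary_windows,
              position_noise_sd = position_noise_sd,
              breeding_origin = breeding_origin,
              breeding_spread = breeding_spread,
              snowline_params = snowline_params,
              landcover_bands = landcover_bands,
              grid = grid, dup_frac = dup_frac,
              season_start_year = season_start_year, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_birds < 1) stop("n_birds must be >= 1")
  if (cfg$frac_female < 0 || cfg$frac_female > 1)
    stop("frac_female must be in [0, 1]")
  if (any(cfg$phase_speeds <= 0)) stop("phase speeds must be positive")
  if (any(cfg$phase_directions < 0 | cfg$phase_directions >= 360))
    stop("phase directions must lie in [0, 360)")
  if (any(cfg$phase_start_sd < 0)) stop("boundary sds must be non-negative")
  if (any(cfg$quick_durations <= 0)) stop("quick durations must be positive")
  if (any(cfg$quick_duration_sd < 0)) stop("duration sds must be non-negative")
  if (cfg$position_noise_sd < 0) stop("position_noise_sd must be non-negative")
  if (is.unsorted(cfg$phase_start_doys, strictly = TRUE))
    stop("mean boundary days must be strictly increasing")
  sp <- cfg$snowline_params
  if (sp$width <= 0) stop("snowline transition width must be positive")
  if (sp$noise_sd < 0) stop("snow noise sd must be non-negative")
  if (length(sp$months) != length(sp$snowline_lat))
    stop("snowline path must give one latitude per month")
  lb <- cfg$landcover_bands
  if (is.unsorted(lb$breaks, strictly = TRUE))
    stop("land-cover band breaks must be strictly increasing (overlapping bands rejected)")
  if (nrow(lb$weights) != length(lb$breaks) - 1)
    stop("need one weight row per land-cover band")
  if (any(lb$weights < 0) || any(abs(rowSums(lb$weights) - 1) > 1e-9))
    stop("each band's class weights must be non-negative and sum to 1")
  if (cfg$dup_frac < 0 || cfg$dup_frac >= 1) stop("dup_frac must be in [0, 1)")
  invisible(cfg)
}

# Deterministic per-bird RNG substream.
.bird_seed <- function(seed, i) as.integer((seed * 1000003 + i * 7919) %% 2147483647)

.truncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (k in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

# Draw one bird's five boundary days: quick-phase start days and
# durations jointly, rejected until all four migration dates fall inside
# their search windows and the full ordering holds.
.draw_boundaries <- function(cfg) {
  bw <- cfg$boundary_windows
  mu <- cfg$phase_start_doys
  sdv <- cfg$phase_start_sd
  # A break day needs two observations on each side of it within the
  # fitted slice, so a date on the outermost days of its window cannot be
  # recovered even without noise; dates are drawn at least 2 days inside.
  inside <- function(x, w) x >= w[1] + 2 && x <= w[2] - 2
  for (k in 1:2000) {
    fs <- round(stats::rnorm(1, mu["fall_start"], sdv["fall_start"]))
    fe <- fs + max(3, round(stats::rnorm(1, cfg$quick_durations["Qf"],
                                         cfg$quick_duration_sd["Qf"])))
    ss <- round(stats::rnorm(1, mu["spring_start"], sdv["spring_start"]))
    se <- ss + max(3, round(stats::rnorm(1, cfg$quick_durations["Qs"],
                                         cfg$quick_duration_sd["Qs"])))
    if (!(inside(fs, bw$fall_start) && inside(fe, bw$fall_end) &&
          inside(ss, bw$spring_start) && inside(se, bw$spring_end)))
      next
    wt <- round(.truncnorm1(mu["winter_turn"], sdv["winter_turn"],
                            fe + 10, ss - 10))
    if (fs < fe && fe < wt && wt < ss && ss < se)
      return(c(fall_start = fs, fall_end = fe, winter_turn = wt,
               spring_start = ss, spring_end = se))
  }
  stop("could not draw ordered phase boundaries; check config")
}

#' Simulate multi-bird annual GPS tracks
#'
#' Each bird breeds at a fixed Arctic origin, then performs four
#' constant-speed phases whose boundary days are drawn per bird: quick
#' fall migration (Qf), slow south-westward winter drift (S1), slow
#' north-eastward return (S2) and quick spring migration (Qs). Within a
#' phase the bird travels along a single great-circle arc whose initial
#' bearing at the phase's start point is the configured direction, so the
#' start-to-end bearing and displacement metrics recover the configured
#' values exactly in the noiseless limit. Observed positions add
#' independent Gaussian noise (degrees) to the true daily position. A
#' configurable fraction of rows is duplicated verbatim so downstream
#' timestamp de-duplication has something to do.
#'
#' @param config A [sim_config()].
#' @return A data.frame with columns `bird_id`, `sex`, `timestamp`
#'   (ISO-8601 UTC, one fix per day at 12:00), `lat`, `lon`. The per-bird
#'   ground truth (origin, sex, boundary days) is attached as
#'   `attr(, "truth")` and the config as `attr(, "config")`.
#' @export
simulate_tracks <- function(config = sim_config()) {
  validate_sim_config(config)
  y0 <- config$season_start_year
  days <- seq(as.Date(sprintf("%d-07-01", y0)),
              as.Date(sprintf("%d-06-30", y0 + 1)), by = "day")
  doys <- date_to_doy(days, season_start_year = y0)
  n_f <- round(config$frac_female * config$n_birds)
  ids <- sprintf("RB%02d", seq_len(config$n_birds))
  sexes <- rep(c("F", "M"), c(n_f, config$n_birds - n_f))

  per_bird <- lapply(seq_len(config$n_birds), function(i) {
    with_local_seed(.bird_seed(config$seed, i), {
      b <- .draw_boundaries(config)
      origin <- c(lat = stats::rnorm(1, config$breeding_origin["lat"],
                                     config$breeding_spread["lat"]),
                  lon = stats::rnorm(1, config$breeding_origin["lon"],
                                     config$breeding_spread["lon"]))
      nd <- length(days)
      lat <- numeric(nd); lon <- numeric(nd)
      lat[1] <- origin["lat"]; lon[1] <- origin["lon"]
      anchor <- c(lat[1], lon[1]); anchor_day <- 1; cur_phase <- NA_character_
      for (d in seq_len(nd - 1)) {
        doy <- doys[d]
        phase <- if (doy >= b["fall_start"] && doy < b["fall_end"]) "Qf"
          else if (doy >= b["fall_end"] && doy < b["winter_turn"]) "S1"
          else if (doy >= b["winter_turn"] && doy < b["spring_start"]) "S2"
          else if (doy >= b["spring_start"] && doy < b["spring_end"]) "Qs"
          else NA_character_
        if (!identical(phase, cur_phase)) {  # new phase starts a new arc
          anchor <- c(lat[d], lon[d]); anchor_day <- d
          cur_phase <- phase
        }
        if (is.na(phase)) {
          lat[d + 1] <- lat[d]; lon[d + 1] <- lon[d]
        } else {
          dest <- destination_point(anchor[1], anchor[2],
                                    config$phase_directions[phase],
                                    config$phase_speeds[phase] *
                                      (d + 1 - anchor_day))
          lat[d + 1] <- dest$lat; lon[d + 1] <- dest$lon
        }
      }
      obs_lat <- lat + stats::rnorm(nd, 0, config$position_noise_sd)
      obs_lon <- lon + stats::rnorm(nd, 0, config$position_noise_sd)
      list(track = data.frame(bird_id = ids[i], sex = sexes[i],
                              timestamp = paste(format(days), "12:00:00"),
                              lat = obs_lat, lon = obs_lon,
                              stringsAsFactors = FALSE),
           truth = data.frame(bird_id = ids[i], sex = sexes[i],
                              origin_lat = unname(origin["lat"]),
                              origin_lon = unname(origin["lon"]),
                              t(b), stringsAsFactors = FALSE))
    })
  })
  tracks <- do.call(rbind, lapply(per_bird, `[[`, "track"))
  truth <- do.call(rbind, lapply(per_bird, `[[`, "truth"))
  rownames(tracks) <- rownames(truth) <- NULL

  if (config$dup_frac > 0) {
    n_dup <- floor(config$dup_frac * nrow(tracks))
    if (n_dup > 0) {
      pick <- with_local_seed(config$seed + 101L,
                              sort(sample.int(nrow(tracks), n_dup)))
      ord <- sort(c(seq_len(nrow(tracks)), pick))
      tracks <- tracks[ord, , drop = FALSE]
      rownames(tracks) <- NULL
    }
  }
  attr(tracks, "truth") <- truth
  attr(tracks, "config") <- config
  tracks
}

#' Simulate monthly fractional snow-cover rasters
#'
#' For each winter month the per-cell snow fraction (percent of days
#' snow-covered) is a logistic function of position relative to that
#' month's snowline, a tilted line in the lat/lon plane:
#' `100 * plogis((lat + tilt * (lon - lon_ref) - snowline_lat) / width)`.
#' Cells north(-east) of the line are snow-covered and cells south(-west)
#' are bare, with optional Gaussian cell noise clipped to [0, 100]. The
#' default snowline advances south-westward from October to February and
#' retreats north-eastward afterwards.
#'
#' @param config A [sim_config()].
#' @return A named list of [fox_raster()] layers, one per month
#'   (`snow_YYYY_MM`), all on the same grid.
#' @export
simulate_snow <- function(config = sim_config()) {
  validate_sim_config(config)
  sp <- config$snowline_params
  g <- .sim_grid(config)
  y0 <- config$season_start_year
  out <- vector("list", length(sp$months))
  for (k in seq_along(sp$months)) {
    m <- sp$months[k]
    yr <- if (m >= 7) y0 else y0 + 1
    tilt <- if (is.null(sp$tilt)) 0 else sp$tilt
    lon_ref <- if (is.null(sp$lon_ref)) 0 else sp$lon_ref
    u <- outer(g$lat, tilt * (g$lon - lon_ref), `+`)
    base <- 100 * stats::plogis(u - sp$snowline_lat[k], scale = sp$width)
    if (sp$noise_sd > 0) {
      noise <- with_local_seed(config$seed + 500L + k,
                               matrix(stats::rnorm(length(base), 0, sp$noise_sd),
                                      nrow = nrow(base)))
      base <- base + noise
    }
    vals <- pmin(pmax(base, 0), 100)
    out[[k]] <- fox_raster(g$lat, g$lon, vals, varname = "snow_pct")
    names(out)[k] <- sprintf("snow_%d_%02d", yr, m)
  }
  attr(out, "months") <- sp$months
  out
}

.sim_grid <- function(config) {
  g <- config$grid
  list(lat = seq(g$lat_range[1] + g$res / 2, g$lat_range[2] - g$res / 2,
                 by = g$res),
       lon = seq(g$lon_range[1] + g$res / 2, g$lon_range[2] - g$res / 2,
                 by = g$res))
}

#' Simulate a latitudinally zoned land-cover raster
#'
#' Latitude bands emulate the vegetation zonation the tracked population
#' crosses: wooded fields (grassland/cropland mosaic) in the mid-latitudes,
#' closed taiga forest, and shrub/grass tundra in the Arctic. Within a band
#' each cell's class is drawn independently with the configured weights.
#'
#' @param config A [sim_config()].
#' @return A categorical [fox_raster()] with classes
#'   forest/grassland/cropland/shrubland/urban.
#' @export
simulate_landcover <- function(config = sim_config()) {
  validate_sim_config(config)
  lb <- config$landcover_bands
  g <- .sim_grid(config)
  classes <- colnames(lb$weights)
  band_of <- findInterval(g$lat, lb$breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
  vals <- with_local_seed(config$seed + 700L, {
    m <- matrix(0L, nrow = length(g$lat), ncol = length(g$lon))
    for (i in seq_along(g$lat)) {
      w <- lb$weights[band_of[i], ]
      m[i, ] <- sample.int(length(classes), length(g$lon), replace = TRUE,
                           prob = w)
    }
    m
  })
  fox_raster(g$lat, g$lon, vals, varname = "landcover", levels = classes)
}

#' Write tracks as a Movebank-dialect CSV
#'
#' Columns `individual-local-identifier`, `timestamp`, `location-lat`,
#' `location-long` (plus `animal-sex` when present), readable by
#' [read_tracks()].
#'
#' @param tracks Data.frame as returned by [simulate_tracks()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  out <- data.frame(`individual-local-identifier` = tracks$bird_id,
                    timestamp = tracks$timestamp,
                    `location-lat` = tracks$lat,
                    `location-long` = tracks$lon,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(tracks$sex)) out$`animal-sex` <- tracks$sex
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
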