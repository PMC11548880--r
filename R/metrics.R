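# Per-phase movement metrics (distance, duration, speed, direction) and
# Table-style population summaries with quick-vs-slow contrasts.

#' Circular mean direction and angular deviation
#'
#' Vector-mean direction of a set of bearings; the circular standard
#' deviation is `sqrt(-2 * log(Rbar))` converted to degrees, where `Rbar`
#' is the mean resultant length. When the resultant length is (numerically)
#' zero the mean direction is undefined and both values are NA with an
#' `undefined` flag.
#'
#' @param directions Bearings in degrees.
#' @return List with `mean_deg` in [0, 360), `circ_sd_deg`, `rbar`,
#'   `undefined`.
#' @examples
#' circular_mean(c(10, 350))  # mean 0
#' @export
circular_mean <- function(directions) {
  directions <- directions[is.finite(directions)]
  if (length(directions) < 1) stop("need at least one direction")
  rad <- directions * pi / 180
  s <- mean(sin(rad)); c <- mean(cos(rad))
  rbar <- sqrt(s^2 + c^2)
  if (rbar < 1e-12)
    return(list(mean_deg = NA_real_, circ_sd_deg = NA_real_, rbar = rbar,
                undefined = TRUE))
  mu <- (atan2(s, c) * 180 / pi + 360) %% 360
  list(mean_deg = mu, circ_sd_deg = sqrt(-2 * log(rbar)) * 180 / pi,
       rbar = rbar, undefined = FALSE)
}

# Signed smallest angular difference a - b in (-180, 180].
.ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Per-phase movement metrics
#'
#' For each bird-season with valid boundaries, the four phases are
#' Qf = fall_start to fall_end, S1 = fall_end to winter_turn,
#' S2 = winter_turn to spring_start, Qs = spring_start to spring_end.
#' Distance is the great-circle distance between the mean daily positions
#' on the two boundary days, duration the day difference, speed their
#' ratio, and direction the initial great-circle bearing. Phases whose
#' boundary-day position is missing are skipped (recorded in
#' `attr(, "skipped")`).
#'
#' @param object A `"foxtrot"` fit, or a daily-track data.frame when
#'   `bounds` is supplied.
#' @param bounds Optional bounds data.frame (as in `fit$bounds`).
#' @return Data.frame with one row per bird-season and phase:
#'   `bird_id`, `season_year`, `phase`, `distance_km`, `duration_days`,
#'   `speed_kmday`, `direction_deg`, plus the endpoint coordinates.
#' @export
phase_metrics <- function(object, bounds = NULL) {
  if (inherits(object, "foxtrot")) {
    daily <- object$data
    bounds <- object$bounds[object$bounds$ok, , drop = FALSE]
  } else {
    daily <- object
    if (is.null(bounds)) stop("supply bounds when not passing a foxtrot fit")
    if (!is.null(bounds$ok)) bounds <- bounds[bounds$ok, , drop = FALSE]
  }
  if (is.null(daily$season_year)) daily$season_year <- NA_integer_
  phases <- rbind(c("Qf", "fall_start", "fall_end"),
                  c("S1", "fall_end", "winter_turn"),
                  c("S2", "winter_turn", "spring_start"),
                  c("Qs", "spring_start", "spring_end"))
  key <- paste(daily$bird_id, daily$season_year)
  rows <- list(); skipped <- character()
  for (r in seq_len(nrow(bounds))) {
    kid <- paste(bounds$bird_id[r], bounds$season_year[r])
    g <- daily[key == kid, , drop = FALSE]
    for (p in seq_len(nrow(phases))) {
      d0 <- bounds[[phases[p, 2]]][r]; d1 <- bounds[[phases[p, 3]]][r]
      if (is.na(d0) || is.na(d1)) next
      p0 <- g[g$doy == d0, , drop = FALSE]
      p1 <- g[g$doy == d1, , drop = FALSE]
      if (nrow(p0) == 0 || nrow(p1) == 0) {
        skipped <- c(skipped, paste(kid, phases[p, 1]))
        next
      }
      dist <- haversine_km(p0$lat[1], p0$lon[1], p1$lat[1], p1$lon[1])
      dur <- d1 - d0
      dir <- if (dist > 0)
        initial_bearing(p0$lat[1], p0$lon[1], p1$lat[1], p1$lon[1])
      else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        bird_id = bounds$bird_id[r], season_year = bounds$season_year[r],
        phase = phases[p, 1], distance_km = dist, duration_days = dur,
        speed_kmday = dist / dur, direction_deg = dir,
        start_lat = p0$lat[1], start_lon = p0$lon[1],
        end_lat = p1$lat[1], end_lon = p1$lon[1],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Population summaries of the phase metrics
#'
#' Per-phase mean and sd of distance, duration and speed across birds;
#' directions are summarised both as circular mean with circular sd and as
#' arithmetic mean with sd. Also returns pooled one-part quick (Qf, Qs)
#' and slow (S1, S2) summaries (per-bird average of its two parts first,
#' then across birds) and the derived contrasts: quick minus slow distance,
#' slow minus quick duration, S1 minus S2 duration, quick/slow speed
#' ratio, and the turn angles between consecutive phases.
#'
#' @param metrics Data.frame from [phase_metrics()].
#' @return A list of class `phase_summary` with elements `per_phase`,
#'   `pooled`, `contrasts`, `turns`, `n_birds`.
#' @export
summarize_phases <- function(metrics) {
  if (length(unique(metrics$bird_id)) < 2)
    stop("need at least 2 birds to summarise")
  msd <- function(v) {
    v <- v[is.finite(v)]
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
      n = length(v))
  }
  per_phase <- do.call(rbind, lapply(c("Qf", "S1", "S2", "Qs"), function(p) {
    m <- metrics[metrics$phase == p, , drop = FALSE]
    cm <- circular_mean(m$direction_deg)
    data.frame(phase = p,
               distance_mean = msd(m$distance_km)["mean"],
               distance_sd = msd(m$distance_km)["sd"],
               duration_mean = msd(m$duration_days)["mean"],
               duration_sd = msd(m$duration_days)["sd"],
               speed_mean = msd(m$speed_kmday)["mean"],
               speed_sd = msd(m$speed_kmday)["sd"],
               direction_circ_mean = cm$mean_deg,
               direction_circ_sd = cm$circ_sd_deg,
               direction_mean = mean(m$direction_deg, na.rm = TRUE),
               direction_sd = stats::sd(m$direction_deg, na.rm = TRUE),
               n = nrow(m), stringsAsFactors = FALSE)
  }))
  rownames(per_phase) <- NULL

  # per-bird one-part averages, then across-bird mean +- sd
  kid <- paste(metrics$bird_id, metrics$season_year)
  pool_one <- function(ph) {
    sub <- metrics[metrics$phase %in% ph, , drop = FALSE]
    sapply(c("distance_km", "duration_days", "speed_kmday"), function(v)
      tapply(sub[[v]], paste(sub$bird_id, sub$season_year), mean))
  }
  q <- pool_one(c("Qf", "Qs")); s <- pool_one(c("S1", "S2"))
  pooled <- data.frame(
    group = c("quick", "slow"),
    distance_mean = c(mean(q[, 1]), mean(s[, 1])),
    distance_sd = c(stats::sd(q[, 1]), stats::sd(s[, 1])),
    duration_mean = c(mean(q[, 2]), mean(s[, 2])),
    duration_sd = c(stats::sd(q[, 2]), stats::sd(s[, 2])),
    speed_mean = c(mean(q[, 3]), mean(s[, 3])),
    speed_sd = c(stats::sd(q[, 3]), stats::sd(s[, 3])),
    stringsAsFactors = FALSE)

  common <- intersect(rownames(q), rownames(s))
  dq <- q[common, , drop = FALSE]; ds <- s[common, , drop = FALSE]
  wide <- function(v) tapply(metrics[[v]], list(kid, metrics$phase), mean)
  dur <- wide("duration_days"); dir <- wide("direction_deg")
  contrasts <- list(
    quick_minus_slow_distance_km = msd(dq[, 1] - ds[, 1]),
    slow_minus_quick_duration_days = msd(ds[, 2] - dq[, 2]),
    s1_minus_s2_duration_days = msd(dur[, "S1"] - dur[, "S2"]),
    quick_over_slow_speed_ratio = msd(dq[, 3] / ds[, 3]))
  turns <- list(
    qf_to_s1 = msd(abs(.ang_diff(dir[, "S1"], dir[, "Qf"]))),
    s2_to_qs = msd(abs(.ang_diff(dir[, "Qs"], dir[, "S2"]))))
  structure(list(per_phase = per_phase, pooled = pooled,
                 contrasts = contrasts, turns = turns,
                 n_birds = length(unique(metrics$bird_id))),
            class = "phase_summary")
}

#' @export
print.phase_summary <- function(x, ...) {
  cat("Phase metrics across", x$n_birds, "birds (mean +- sd):\n\n")
  pp <- x$per_phase
  for (i in seq_len(nrow(pp)))
    cat(sprintf("  %-2s  %6.0f +- %3.0f km  %5.1f +- %4.1f d  %5.1f +- %3.1f km/d  dir %5.1f deg\n",
                pp$phase[i], pp$distance_mean[i], pp$distance_sd[i],
                pp$duration_mean[i], pp$duration_sd[i],
                pp$speed_mean[i], pp$speed_sd[i], pp$direction_circ_mean[i]))
  po <- x$pooled
  cat("\nPooled one-part phases:\n")
  for (i in 1:2)
    cat(sprintf("  %-5s %6.0f +- %3.0f km  %5.1f +- %4.1f d  %5.1f +- %3.1f km/d\n",
                po$group[i], po$distance_mean[i], po$distance_sd[i],
                po$duration_mean[i], po$duration_sd[i],
                po$speed_mean[i], po$speed_sd[i]))
  ct <- x$contrasts
  cat(sprintf("\nQuick is %.0f +- %.0f km longer and %.0f +- %.0f days shorter than slow\n",
              ct$quick_minus_slow_distance_km["mean"],
              ct$quick_minus_slow_distance_km["sd"],
              ct$slow_minus_quick_duration_days["mean"],
              ct$slow_minus_quick_duration_days["sd"]))
  invisible(x)
}

#' Effect of sex on migration distance
#'
#' Per-sex mean and sd of the per-bird quick-phase one-part migration
#' distance with a Welch two-sample test. Skipped (with a flag) when a sex
#' has fewer than 3 birds.
#'
#' @param metrics Data.frame from [phase_metrics()].
#' @param sex_table Data.frame with columns `bird_id`, `sex`.
#' @return A list with `groups` (per-sex mean, sd, n), `test` (a
#'   `fox_test` or NULL), `skipped`.
#' @export
sex_distance_comparison <- function(metrics, sex_table) {
  q <- metrics[metrics$phase %in% c("Qf", "Qs"), , drop = FALSE]
  per_bird <- tapply(q$distance_km, q$bird_id, mean)
  sex <- sex_table$sex[match(names(per_bird), sex_table$bird_id)]
  groups <- do.call(rbind, lapply(unique(sex[!is.na(sex)]), function(s) {
    v <- per_bird[which(sex == s)]
    data.frame(sex = s, mean_km = mean(v),
               sd_km = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  counts <- table(sex)
  if (length(counts) < 2 || any(counts < 3))
    return(list(groups = groups, test = NULL, skipped = TRUE))
  ss <- names(counts)[1:2]
  list(groups = groups,
       test = two_sample_t(per_bird[which(sex == ss[1])],
                           per_bird[which(sex == ss[2])]),
       skipped = FALSE)
}
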