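# Piecewise-regression breakpoint search: each of the four migration
# dates is the integer day that minimises the residual standard error of
# a two-segment linear fit of latitude on the consecutive day axis, and
# the mid-winter turn is the day of lowest mean daily latitude.

#' Migration-date search windows
#'
#' Default consecutive-DOY windows for the four breakpoints: fall start
#' 5 Sep - 5 Oct (248-278), fall end 5 Oct - 5 Nov (278-309), spring start
#' 10 Apr - 10 May (465-495), spring end 10 May - 10 Jun (495-526).
#'
#' @param fit_margin Days of data included on each side beyond the window
#'   when fitting (default 30).
#' @return A list of `c(lo, hi)` windows with a `fit_margin` attribute.
#' @export
migration_windows <- function(fit_margin = 30) {
  w <- list(fall_start = c(248, 278), fall_end = c(278, 309),
            spring_start = c(465, 495), spring_end = c(495, 526))
  stopifnot(all(vapply(w, function(x) x[1] < x[2], logical(1))),
            fit_margin >= 0)
  attr(w, "fit_margin") <- fit_margin
  w
}

#' Simple linear fit of latitude on day
#'
#' Ordinary least squares with residual standard error
#' `sqrt(rss / (n - 2))`.
#'
#' @param doys,lats Numeric vectors (>= 3 points, not all days equal).
#' @return List with `slope`, `intercept`, `rss`, `rse`, `n`.
#' @export
fit_simple <- function(doys, lats) {
  ok <- is.finite(doys) & is.finite(lats)
  doys <- doys[ok]; lats <- lats[ok]
  n <- length(doys)
  if (n < 3) stop("need at least 3 points")
  if (stats::var(doys) == 0) stop("degenerate fit: all days equal")
  fit <- stats::lm.fit(cbind(1, doys), lats)
  rss <- sum(fit$residuals^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       rss = rss, rse = sqrt(rss / (n - 2)), n = n)
}

#' Two-segment piecewise fit at a candidate break day
#'
#' Independent OLS lines for days `< break_doy` and days `>= break_doy`
#' (4 parameters, discontinuity allowed); residual standard error is
#' `sqrt((rss_left + rss_right) / (n - 4))`. A candidate with fewer than
#' 2 points on either side, or n <= 4 overall, is infeasible and returns
#' NULL.
#'
#' @param doys,lats Numeric vectors.
#' @param break_doy Candidate break day.
#' @return List with `rss`, `rse`, `n`, `break_doy`, or NULL if
#'   infeasible.
#' @export
fit_piecewise <- function(doys, lats, break_doy) {
  ok <- is.finite(doys) & is.finite(lats)
  doys <- doys[ok]; lats <- lats[ok]
  left <- doys < break_doy
  nl <- sum(left); nr <- sum(!left)
  n <- nl + nr
  if (nl < 2 || nr < 2 || n <= 4) return(NULL)
  if (stats::var(doys[left]) == 0 || stats::var(doys[!left]) == 0) return(NULL)
  fl <- stats::lm.fit(cbind(1, doys[left]), lats[left])
  fr <- stats::lm.fit(cbind(1, doys[!left]), lats[!left])
  rss <- sum(fl$residuals^2) + sum(fr$residuals^2)
  list(rss = rss, rse = sqrt(rss / (n - 4)), n = n, break_doy = break_doy)
}

#' Breakpoint search within a window
#'
#' Evaluates every integer day in the window as a candidate break on the
#' data slice `[lo - fit_margin[1], hi + fit_margin[2]]`, keeps the
#' feasible candidate with minimal residual standard error (ties go to the
#' earliest day), and attaches the nested F test of the piecewise model
#' against the single-line model on the same slice. A scalar `fit_margin`
#' extends the slice on both sides; [estimate_phase_bounds()] extends each
#' date's slice only away from the adjacent migration date so the fitted
#' slice contains a single slope change.
#'
#' @param daily One bird-season of daily positions (`doy`, `lat`).
#' @param window `c(lo, hi)` consecutive-DOY bounds.
#' @param fit_margin Days of data beyond the window used in the fits;
#'   length 1 (both sides) or 2 (below, above).
#' @return A list (`break_doy`, `rse_piecewise`, `rse_simple`, `f_stat`,
#'   `p_value`, `n_obs`).
#' @export
search_break <- function(daily, window, fit_margin = 30) {
  stopifnot(window[1] < window[2], all(fit_margin >= 0))
  fit_margin <- rep_len(fit_margin, 2)
  sl <- daily[daily$doy >= window[1] - fit_margin[1] &
                daily$doy <= window[2] + fit_margin[2], , drop = FALSE]
  if (nrow(sl) < 5)
    stop("track does not cover the search window (", window[1], "-",
         window[2], ")")
  candidates <- seq(ceiling(window[1]), floor(window[2]))
  best <- NULL
  for (b in candidates) {
    f <- fit_piecewise(sl$doy, sl$lat, b)
    if (is.null(f)) next
    # strict improvement beyond numerical noise, so exact ties resolve to
    # the earliest candidate day
    if (is.null(best) || f$rse < best$rse - 1e-9) best <- f
  }
  if (is.null(best)) stop("no feasible break candidate in window")
  simple <- fit_simple(sl$doy, sl$lat)
  ft <- f_test_nested(simple$rss, best$rss, df0 = 2, df1 = 4, n = best$n)
  list(break_doy = best$break_doy, rse_piecewise = best$rse,
       rse_simple = simple$rse, rss_piecewise = best$rss,
       rss_simple = simple$rss, f_stat = ft$statistic,
       p_value = ft$p_value, n_obs = best$n)
}

#' Mid-winter turning day
#'
#' The day of lowest mean daily latitude between the end of fall migration
#' and the start of spring migration; ties go to the earliest day.
#'
#' @param daily One bird-season of daily positions.
#' @param fall_end,spring_start Consecutive DOY bounds of the winter.
#' @return The consecutive DOY of the latitude minimum.
#' @export
winter_turn <- function(daily, fall_end, spring_start) {
  sl <- daily[daily$doy >= fall_end & daily$doy <= spring_start, , drop = FALSE]
  if (nrow(sl) == 0) stop("no positions between fall_end and spring_start")
  sl$doy[which.min(sl$lat)]
}

#' Estimate the five phase-boundary days for one bird-season
#'
#' Runs the four breakpoint searches and the winter-turn minimum, and
#' validates the ordering fall_start < fall_end < winter_turn <
#' spring_start < spring_end. Each date's fitted slice extends
#' `fit_margin` days beyond its window only on the side away from the
#' adjacent migration date (before the window for fall start and spring
#' start, after it for fall end and spring end), so the two-segment model
#' sees one slope change. Boundaries whose window the track does not
#' cover are returned as NA (partial result); an ordering violation is
#' reported via `ok = FALSE`.
#'
#' @param daily One bird-season of daily positions.
#' @param windows A [migration_windows()] list.
#' @param fit_margin Fitted-slice margin in days.
#' @return A list with `bounds` (named numeric, possibly NA), `fits`
#'   (per-boundary search results), `ok`, and `reason` when not ok.
#' @export
estimate_phase_bounds <- function(daily, windows = migration_windows(),
                                  fit_margin = attr(windows, "fit_margin")) {
  if (is.null(fit_margin)) fit_margin <- 30
  fits <- list()
  b <- c(fall_start = NA_real_, fall_end = NA_real_, winter_turn = NA_real_,
         spring_start = NA_real_, spring_end = NA_real_)
  margins <- list(fall_start = c(fit_margin, 0), fall_end = c(0, fit_margin),
                  spring_start = c(fit_margin, 0),
                  spring_end = c(0, fit_margin))
  for (lab in c("fall_start", "fall_end", "spring_start", "spring_end")) {
    res <- tryCatch(search_break(daily, windows[[lab]], margins[[lab]]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      fits[[lab]] <- list(error = conditionMessage(res))
    } else {
      fits[[lab]] <- res
      b[lab] <- res$break_doy
    }
  }
  if (!is.na(b["fall_end"]) && !is.na(b["spring_start"]) &&
      b["fall_end"] < b["spring_start"]) {
    b["winter_turn"] <- tryCatch(
      winter_turn(daily, b["fall_end"], b["spring_start"]),
      error = function(e) NA_real_)
  }
  have <- b[!is.na(b)]
  ok <- length(have) < 2 || !is.unsorted(have, strictly = TRUE)
  list(bounds = b, fits = fits, ok = ok,
       reason = if (!ok) "phase boundaries out of order" else NULL)
}

#' Fit the foxtrot migration model to daily tracks
#'
#' The main fitting function. For every bird-season in `data` it estimates
#' the four migration dates by piecewise-regression breakpoint search and
#' the mid-winter turn as the latitude minimum, giving the five-knot
#' annual phase structure: breeding, quick fall (Qf), slow south-westward
#' (S1), slow north-eastward (S2), quick spring (Qs), breeding. Birds
#' whose estimated boundaries violate the phase ordering are excluded from
#' summaries and listed in the returned object.
#'
#' @param data Daily-track data.frame from [preprocess_tracks()]
#'   (columns `bird_id`, `season_year`, `doy`, `lat`, `lon`).
#' @param windows Search windows, see [migration_windows()].
#' @param fit_margin Days of data used beyond each window in the fits.
#' @return An object of class `"foxtrot"`: list with `bounds` (one row per
#'   bird-season: five boundary DOYs plus per-date fit diagnostics),
#'   `fits`, `data`, `windows`, `failed`.
#' @seealso [summary.foxtrot()], [phase_metrics()], [plot.foxtrot()]
#' @examples
#' cfg <- sim_config(n_birds = 3, seed = 42)
#' daily <- preprocess_tracks(simulate_tracks(cfg))
#' fit <- fit_foxtrot(daily)
#' coef(fit)
#' @export
fit_foxtrot <- function(data, windows = migration_windows(),
                        fit_margin = attr(windows, "fit_margin")) {
  stopifnot(all(c("bird_id", "doy", "lat", "lon") %in% names(data)))
  if (is.null(data$season_year)) data$season_year <- NA_integer_
  if (is.null(fit_margin)) fit_margin <- 30
  key <- paste(data$bird_id, data$season_year)
  groups <- split(data, key)
  rows <- list(); fits <- list(); failed <- character()
  for (g in groups) {
    est <- estimate_phase_bounds(g, windows, fit_margin)
    id <- g$bird_id[1]; sy <- g$season_year[1]
    kid <- paste(id, sy)
    fits[[kid]] <- est$fits
    if (!est$ok) failed <- c(failed, kid)
    pv <- vapply(c("fall_start", "fall_end", "spring_start", "spring_end"),
                 function(l) {
                   f <- est$fits[[l]]
                   if (is.null(f$p_value)) NA_real_ else f$p_value
                 }, numeric(1))
    rows[[kid]] <- data.frame(bird_id = id, season_year = sy,
                              t(est$bounds),
                              p_fall_start = pv[1], p_fall_end = pv[2],
                              p_spring_start = pv[3], p_spring_end = pv[4],
                              ok = est$ok, stringsAsFactors = FALSE)
  }
  bounds <- do.call(rbind, rows)
  rownames(bounds) <- NULL
  structure(list(bounds = bounds, fits = fits, data = data,
                 windows = windows, fit_margin = fit_margin,
                 failed = failed),
            class = "foxtrot")
}

.phase_of_doy <- function(doy, b) {
  out <- rep(NA_character_, length(doy))
  out[doy >= b["fall_start"] & doy <= b["fall_end"]] <- "Qf"
  out[doy > b["fall_end"] & doy <= b["winter_turn"]] <- "S1"
  out[doy > b["winter_turn"] & doy < b["spring_start"]] <- "S2"
  out[doy >= b["spring_start"] & doy <= b["spring_end"]] <- "Qs"
  out[doy < b["fall_start"]] <- "breeding"
  out[doy > b["spring_end"]] <- "post"
  out
}

#' @export
print.foxtrot <- function(x, ...) {
  cat("Foxtrot migration fit:", nrow(x$bounds), "bird-season(s)\n")
  okb <- x$bounds[x$bounds$ok, , drop = FALSE]
  if (nrow(okb)) {
    m <- colMeans(okb[, c("fall_start", "fall_end", "winter_turn",
                          "spring_start", "spring_end")], na.rm = TRUE)
    cat("Mean boundary days (consecutive DOY):\n")
    print(round(m, 1))
  }
  if (length(x$failed))
    cat("Excluded (ordering violation):", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' Coefficients of a foxtrot fit
#'
#' @param object A `"foxtrot"` object.
#' @param ... Unused.
#' @return Matrix of the five boundary days, one row per bird-season.
#' @export
coef.foxtrot <- function(object, ...) {
  m <- as.matrix(object$bounds[, c("fall_start", "fall_end", "winter_turn",
                                   "spring_start", "spring_end")])
  rownames(m) <- paste(object$bounds$bird_id, object$bounds$season_year)
  m
}

# Per-phase OLS of latitude on day used by predict/residuals: the fitted
# annual curve is piecewise linear with independent segments between the
# estimated knots.
.segment_fits <- function(object, kid) {
  g <- object$data[paste(object$data$bird_id, object$data$season_year) == kid, ]
  b <- object$bounds[paste(object$bounds$bird_id,
                           object$bounds$season_year) == kid, ]
  bv <- unlist(b[1, c("fall_start", "fall_end", "winter_turn",
                      "spring_start", "spring_end")])
  ph <- .phase_of_doy(g$doy, bv)
  fits <- lapply(split(seq_len(nrow(g)), ph), function(idx) {
    if (length(idx) < 2 || stats::var(g$doy[idx]) == 0)
      return(list(int = mean(g$lat[idx]), slo = 0))
    f <- stats::lm.fit(cbind(1, g$doy[idx]), g$lat[idx])
    list(int = unname(f$coefficients[1]), slo = unname(f$coefficients[2]))
  })
  list(data = g, phase = ph, fits = fits)
}

#' Fitted piecewise-linear latitudes
#'
#' Predicts the fitted latitude of the annual piecewise-linear curve
#' (independent OLS line per phase between the estimated boundary days)
#' at each observed day.
#'
#' @param object A `"foxtrot"` object.
#' @param ... Unused.
#' @return Numeric vector aligned with `object$data` rows.
#' @export
predict.foxtrot <- function(object, ...) {
  out <- rep(NA_real_, nrow(object$data))
  key <- paste(object$data$bird_id, object$data$season_year)
  for (kid in unique(key)) {
    sf <- .segment_fits(object, kid)
    idx <- which(key == kid)
    for (p in names(sf$fits)) {
      sel <- idx[which(sf$phase == p)]
      out[sel] <- sf$fits[[p]]$int + sf$fits[[p]]$slo * object$data$doy[sel]
    }
  }
  out
}

#' @export
fitted.foxtrot <- function(object, ...) predict(object, ...)

#' @export
residuals.foxtrot <- function(object, ...) object$data$lat - predict(object)

#' Summary of a foxtrot fit
#'
#' Across-bird mean and sd of each boundary day, mean coordinates at each
#' boundary, and the share of piecewise-vs-simple model comparisons
#' significant at p < 0.001.
#'
#' @param object A `"foxtrot"` object.
#' @param ... Unused.
#' @return An object of class `summary.foxtrot`.
#' @export
summary.foxtrot <- function(object, ...) {
  okb <- object$bounds[object$bounds$ok, , drop = FALSE]
  labs <- c("fall_start", "fall_end", "winter_turn", "spring_start",
            "spring_end")
  tab <- data.frame(boundary = labs,
                    mean_doy = NA_real_, sd_doy = NA_real_, n = NA_integer_,
                    mean_lat = NA_real_, sd_lat = NA_real_,
                    mean_lon = NA_real_, sd_lon = NA_real_)
  key <- paste(object$data$bird_id, object$data$season_year)
  for (i in seq_along(labs)) {
    v <- okb[[labs[i]]]
    v <- v[!is.na(v)]
    tab$mean_doy[i] <- mean(v); tab$sd_doy[i] <- stats::sd(v)
    tab$n[i] <- length(v)
    pos <- do.call(rbind, lapply(seq_len(nrow(okb)), function(r) {
      kid <- paste(okb$bird_id[r], okb$season_year[r])
      d <- object$data[key == kid & object$data$doy == okb[[labs[i]]][r], ,
                       drop = FALSE]
      if (nrow(d)) c(d$lat[1], d$lon[1]) else c(NA_real_, NA_real_)
    }))
    tab$mean_lat[i] <- mean(pos[, 1], na.rm = TRUE)
    tab$sd_lat[i] <- stats::sd(pos[, 1], na.rm = TRUE)
    tab$mean_lon[i] <- mean(pos[, 2], na.rm = TRUE)
    tab$sd_lon[i] <- stats::sd(pos[, 2], na.rm = TRUE)
  }
  pcols <- c("p_fall_start", "p_fall_end", "p_spring_start", "p_spring_end")
  pvals <- unlist(okb[, pcols])
  structure(list(boundaries = tab,
                 n_fitted = nrow(object$bounds),
                 n_excluded = length(object$failed),
                 frac_p_lt_001 = mean(pvals < 0.001, na.rm = TRUE)),
            class = "summary.foxtrot")
}

#' @export
print.summary.foxtrot <- function(x, ...) {
  cat("Foxtrot migration fit:", x$n_fitted, "bird-season(s),",
      x$n_excluded, "excluded\n\n")
  tab <- x$boundaries
  tab[, -1] <- round(tab[, -1], 2)
  print(tab, row.names = FALSE)
  cat(sprintf("\nPiecewise vs simple model: %.0f%% of %s comparisons with p < 0.001\n",
              100 * x$frac_p_lt_001, "per-date"))
  invisible(x)
}

#' Plot a foxtrot fit
#'
#' Latitude against the consecutive day axis for each bird (grey), the
#' population mean (red), and the mean boundary days as vertical lines.
#'
#' @param x A `"foxtrot"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.foxtrot <- function(x, ...) {
  d <- x$data
  graphics::plot(range(d$doy), range(d$lat), type = "n",
                 xlab = "consecutive day of year", ylab = "latitude (deg N)",
                 ...)
  for (kid in unique(paste(d$bird_id, d$season_year))) {
    g <- d[paste(d$bird_id, d$season_year) == kid, ]
    graphics::lines(g$doy, g$lat, col = grDevices::grey(0.75))
  }
  mn <- tapply(d$lat, d$doy, mean)
  graphics::lines(as.numeric(names(mn)), mn, col = "red", lwd = 2)
  okb <- x$bounds[x$bounds$ok, , drop = FALSE]
  for (lab in c("fall_start", "fall_end", "spring_start", "spring_end"))
    graphics::abline(v = mean(okb[[lab]], na.rm = TRUE), lty = 2)
  graphics::abline(v = mean(okb$winter_turn, na.rm = TRUE), lty = 2,
                   col = "blue")
  invisible(x)
}
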