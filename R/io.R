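# Reading Movebank-dialect tracking tables and reducing them to mean
# daily positions on a consecutive day-of-year axis.

#' Read a Movebank-dialect tracking table
#'
#' Expects columns `individual-local-identifier`, `timestamp`,
#' `location-lat`, `location-long` (an optional `animal-sex` column is
#' carried through). Rows with unparseable timestamps or out-of-bounds
#' coordinates are dropped with a warning giving the count.
#'
#' @param path Path to a delimited text file.
#' @return A data.frame of track points: `bird_id`, `timestamp`
#'   (POSIXct, UTC), `lat`, `lon` and possibly `sex`.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("individual-local-identifier", "timestamp", "location-lat",
           "location-long")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  lat <- suppressWarnings(as.numeric(raw$`location-lat`))
  lon <- suppressWarnings(as.numeric(raw$`location-long`))
  ok <- !is.na(ts) & !is.na(lat) & !is.na(lon) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180
  if (any(!ok))
    warning(sum(!ok), " row(s) dropped (unparseable or out-of-bounds)")
  out <- data.frame(bird_id = as.character(raw$`individual-local-identifier`)[ok],
                    timestamp = ts[ok], lat = lat[ok], lon = lon[ok],
                    stringsAsFactors = FALSE)
  if ("animal-sex" %in% names(raw)) out$sex <- as.character(raw$`animal-sex`)[ok]
  out
}

#' Remove duplicated timestamps
#'
#' For rows sharing the same bird and timestamp only the first occurrence
#' in file order is kept. Identical timestamps on different birds are not
#' duplicates.
#'
#' @param points Track points as from [read_tracks()].
#' @return The de-duplicated data.frame.
#' @export
dedupe_timestamps <- function(points) {
  ts_key <- if (inherits(points$timestamp, "POSIXt"))
    format(points$timestamp, "%Y-%m-%d %H:%M:%OS3")
  else as.character(points$timestamp)
  keep <- !duplicated(paste(points$bird_id, ts_key))
  out <- points[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean daily positions
#'
#' Arithmetic mean of latitude and of longitude per bird per UTC calendar
#' date. Longitudes are averaged arithmetically, which is accurate when a
#' day's fixes span much less than a degree and does not handle the
#' antimeridian.
#'
#' @param points De-duplicated track points.
#' @return A data.frame `bird_id`, `date` (Date), `lat`, `lon` (plus `sex`
#'   if present), one row per bird per date.
#' @export
daily_means <- function(points) {
  day <- as.Date(points$timestamp, tz = "UTC")
  key <- paste(points$bird_id, day)
  lat <- tapply(points$lat, key, mean)
  lon <- tapply(points$lon, key, mean)
  ids <- do.call(rbind, strsplit(names(lat), " (?=[0-9]{4}-)", perl = TRUE))
  out <- data.frame(bird_id = ids[, 1], date = as.Date(ids[, 2]),
                    lat = as.numeric(lat), lon = as.numeric(lon),
                    stringsAsFactors = FALSE)
  if (!is.null(points$sex)) {
    sex_map <- tapply(points$sex, points$bird_id, function(s) s[1])
    out$sex <- unname(sex_map[out$bird_id])
  }
  out <- out[order(out$bird_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consecutive day-of-year
#'
#' Day-of-year under the fixed 365-day (non-leap) calendar, continued past
#' 31 December within a biological season: dates in the calendar year
#' after `season_start_year` get 365 + DOY. 29 February is assigned day 60
#' (it shares the index of 1 March under this convention). With
#' `season_start_year = NULL` the plain 1..365 calendar index is returned.
#'
#' @param date A Date vector.
#' @param season_start_year Calendar year the season started in, or NULL.
#' @return Integer vector of day indices.
#' @examples
#' date_to_doy(as.Date("2021-09-28"))  # 271
#' date_to_doy(as.Date("2022-05-15"), season_start_year = 2021)  # 500
#' @export
date_to_doy <- function(date, season_start_year = NULL) {
  date <- as.Date(date)
  mo <- as.integer(format(date, "%m"))
  dy <- as.integer(format(date, "%d"))
  cum <- c(0, 31, 59, 90, 120, 151, 181, 212, 243, 273, 304, 334)
  doy <- cum[mo] + pmin(dy, ifelse(mo == 2, 29, 31))
  doy[mo == 2 & dy == 29] <- 60L  # leap day folded onto 1 March's index
  if (!is.null(season_start_year)) {
    yr <- as.integer(format(date, "%Y"))
    doy <- doy + 365L * (yr - as.integer(season_start_year))
  }
  as.integer(doy)
}

#' Assign biological seasons and the consecutive day axis
#'
#' A biological season runs from 1 July to 30 June so that fall migration,
#' the whole winter and spring migration share one `season_year` (the
#' calendar year of the season's July). Adds `season_year` and the
#' consecutive `doy` to daily rows.
#'
#' @param daily Data.frame from [daily_means()].
#' @return The input with `season_year` and `doy` columns, ordered by
#'   bird and date; `doy` is strictly increasing within each bird-season
#'   (except across a leap day, see [date_to_doy()]).
#' @export
assign_season <- function(daily) {
  yr <- as.integer(format(daily$date, "%Y"))
  mo <- as.integer(format(daily$date, "%m"))
  daily$season_year <- ifelse(mo >= 7, yr, yr - 1L)
  daily$doy <- date_to_doy(daily$date, season_start_year = daily$season_year)
  daily <- daily[order(daily$bird_id, daily$season_year, daily$date), ,
                 drop = FALSE]
  rownames(daily) <- NULL
  cols <- c("bird_id", "season_year", "date", "doy", "lat", "lon")
  daily[, c(cols, setdiff(names(daily), cols)), drop = FALSE]
}

#' Full pre-processing pipeline
#'
#' `read_tracks()` (when given a path), de-duplication, daily means and
#' season assignment in one call.
#'
#' @param x A file path or a track-point data.frame.
#' @return A daily-track data.frame
#'   (`bird_id, season_year, date, doy, lat, lon`, ...).
#' @export
preprocess_tracks <- function(x) {
  pts <- if (is.character(x)) read_tracks(x) else x
  if (!inherits(pts$timestamp, "POSIXct"))
    pts$timestamp <- as.POSIXct(pts$timestamp, tz = "UTC")
  assign_season(daily_means(dedupe_timestamps(pts)))
}
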