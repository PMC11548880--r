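# Land-cover annotation of mean daily positions and quick-vs-slow phase
# composition.

#' Merge raw land-cover codes into the five analysis classes
#'
#' Maps a MODIS-style LAI land-cover legend onto the five classes used in
#' the analysis: the four forest types and savanna collapse to `forest`;
#' water bodies, non-vegetated land and unclassified cells are `EXCLUDED`
#' (dropped from composition denominators). Character input already using
#' the five class names passes through unchanged.
#'
#' @param raw_class Integer codes of the legend below, or class names.
#' @return Character vector over
#'   `c("forest", "grassland", "cropland", "shrubland", "urban", "EXCLUDED")`.
#' @section Legend:
#' 0 water, 1 grassland, 2 shrubland, 3 cropland, 4 savanna,
#' 5 evergreen broadleaf forest, 6 deciduous broadleaf forest,
#' 7 evergreen needleleaf forest, 8 deciduous needleleaf forest,
#' 9 non-vegetated, 10 urban, 255 unclassified.
#' @export
merge_classes <- function(raw_class) {
  final <- c("forest", "grassland", "cropland", "shrubland", "urban")
  if (is.character(raw_class) || is.factor(raw_class)) {
    raw_class <- as.character(raw_class)
    bad <- !(raw_class %in% c(final, "EXCLUDED"))
    if (any(bad))
      stop("unknown land-cover name(s): ",
           paste(unique(raw_class[bad]), collapse = ", "),
           "; expected one of ", paste(final, collapse = ", "))
    return(raw_class)
  }
  legend <- c(`0` = "EXCLUDED", `1` = "grassland", `2` = "shrubland",
              `3` = "cropland", `4` = "forest", `5` = "forest",
              `6` = "forest", `7` = "forest", `8` = "forest",
              `9` = "EXCLUDED", `10` = "urban", `255` = "EXCLUDED")
  key <- as.character(raw_class)
  bad <- !(key %in% names(legend))
  if (any(bad))
    stop("unknown land-cover code(s): ",
         paste(unique(key[bad]), collapse = ", "),
         "; legend codes are ", paste(names(legend), collapse = ", "))
  unname(legend[key])
}

#' Annotate daily positions with land cover
#'
#' Containing-cell lookup (no interpolation) of each position in a
#' categorical raster. Positions outside the raster extent are dropped
#' with a warning; positions on an excluded class are kept but flagged so
#' composition denominators can omit them.
#'
#' @param landcover A categorical [fox_raster()] (integer codes with
#'   `levels`, or codes interpretable by [merge_classes()]).
#' @param daily Daily-track data.frame.
#' @return `daily` with a `landcover` column (five-class name or
#'   `"EXCLUDED"`); out-of-extent rows removed.
#' @export
annotate_positions <- function(landcover, daily) {
  stopifnot(inherits(landcover, "fox_raster"))
  cls <- raster_lookup(landcover, daily$lat, daily$lon)
  out <- is.na(cls)
  if (any(out))
    warning(sum(out), " position(s) outside the raster extent dropped")
  daily <- daily[!out, , drop = FALSE]
  daily$landcover <- merge_classes(cls[!out])
  rownames(daily) <- NULL
  daily
}

#' Quick-vs-slow land-cover composition
#'
#' Per bird-season, the percentage of annotated mean daily positions in
#' each class, separately for the pooled quick phases (Qf and Qs,
#' boundary days inclusive) and the pooled slow phases (between fall end
#' and spring start). Positions on excluded classes are removed from the
#' denominators. Population summaries give mean and sd per class, and a
#' paired t contrast of the per-bird quick minus slow share. Classes
#' annotated for fewer than `min_birds_per_class` birds are flagged as
#' unreliable rather than tested.
#'
#' @param annotated Output of [annotate_positions()].
#' @param bounds Bounds data.frame from a [fit_foxtrot()] object
#'   (`fit$bounds`).
#' @param min_birds_per_class Minimum birds with the class present in
#'   both phase groups for the contrast (default 5).
#' @return A list with `per_bird` (bird x phase_group x class percent),
#'   `summary` (class, phase_group, mean, sd, n_birds), `contrasts`
#'   (per-class paired tests or flag).
#' @export
phase_composition <- function(annotated, bounds, min_birds_per_class = 5) {
  if (!is.null(bounds$ok)) bounds <- bounds[bounds$ok, , drop = FALSE]
  classes <- c("forest", "grassland", "cropland", "shrubland", "urban")
  key <- paste(annotated$bird_id, annotated$season_year)
  rows <- list()
  for (r in seq_len(nrow(bounds))) {
    kid <- paste(bounds$bird_id[r], bounds$season_year[r])
    g <- annotated[key == kid, , drop = FALSE]
    if (nrow(g) == 0) next
    bv <- unlist(bounds[r, c("fall_start", "fall_end", "winter_turn",
                             "spring_start", "spring_end")])
    ph <- .phase_of_doy(g$doy, bv)
    grp <- ifelse(ph %in% c("Qf", "Qs"), "quick",
                  ifelse(ph %in% c("S1", "S2"), "slow", NA))
    for (pg in c("quick", "slow")) {
      sel <- !is.na(grp) & grp == pg & g$landcover != "EXCLUDED"
      if (!any(sel)) next
      tab <- table(factor(g$landcover[sel], levels = classes))
      pct <- 100 * as.numeric(tab) / sum(tab)
      rows[[length(rows) + 1]] <- data.frame(
        bird_id = bounds$bird_id[r], season_year = bounds$season_year[r],
        phase_group = pg, class = classes, percent = pct,
        n_positions = sum(sel), stringsAsFactors = FALSE)
    }
  }
  per_bird <- do.call(rbind, rows)
  rownames(per_bird) <- NULL

  summ <- do.call(rbind, lapply(c("quick", "slow"), function(pg) {
    do.call(rbind, lapply(classes, function(cl) {
      v <- per_bird$percent[per_bird$phase_group == pg & per_bird$class == cl]
      data.frame(phase_group = pg, class = cl, mean = mean(v),
                 sd = stats::sd(v), n_birds = length(v),
                 stringsAsFactors = FALSE)
    }))
  }))

  contrasts <- lapply(classes, function(cl) {
    sub <- per_bird[per_bird$class == cl, , drop = FALSE]
    kq <- sub[sub$phase_group == "quick", ]
    ks <- sub[sub$phase_group == "slow", ]
    common <- intersect(paste(kq$bird_id, kq$season_year),
                        paste(ks$bird_id, ks$season_year))
    present <- sum(kq$percent[match(common, paste(kq$bird_id, kq$season_year))] > 0 |
                     ks$percent[match(common, paste(ks$bird_id, ks$season_year))] > 0)
    if (present < min_birds_per_class || length(common) < 3)
      return(list(class = cl, flagged = TRUE, n_birds = present, test = NULL))
    d <- kq$percent[match(common, paste(kq$bird_id, kq$season_year))] -
      ks$percent[match(common, paste(ks$bird_id, ks$season_year))]
    list(class = cl, flagged = FALSE, n_birds = present, test = paired_t(d))
  })
  names(contrasts) <- classes
  list(per_bird = per_bird, summary = summ, contrasts = contrasts)
}
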