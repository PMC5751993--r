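#' Build a species detection matrix
#'
#' Collapses time-stamped photo events into a stations x occasions binary
#' detection history for one species. The survey window is cut into occasions
#' of `occasion_days` days (a final short occasion, if any, is kept and its
#' reduced effort recorded). An entry is 1 if at least one photo event of the
#' species occurred at the station during the occasion, 0 if the station was
#' active but recorded none, and `NA` exactly where the station had zero
#' active days in the occasion.
#'
#' @param survey a [ct_survey()] bundle.
#' @param species species name (must match the photo table's labels; a species
#'   absent from all events yields an all-zero matrix with a warning).
#' @param occasion_days days per occasion; default taken from the bundle's
#'   config (10).
#' @return an object of class `detection_matrix`: list with `species`,
#'   `stations`, `occasions`, `y` (stations x occasions in 0/1/NA) and
#'   `effort` (active days per station-occasion).
#' @export
build_detection_matrix <- function(survey, species, occasion_days = NULL) {
  stopifnot(inherits(survey, "ct_survey"), is.character(species),
            length(species) == 1)
  cfg <- survey$config
  occasion_days <- as.integer(occasion_days %||% cfg$occ_occasion_days)
  stopifnot(occasion_days >= 1)
  days <- cfg$survey_days
  n_occ <- as.integer(ceiling(days / occasion_days))
  if (days %% occasion_days != 0)
    message(sprintf(
      "note: %d-day window not divisible by %d-day occasions; final occasion has %d day(s)",
      days, occasion_days, days %% occasion_days))
  st <- survey$stations
  occ_of_day <- function(d) pmin((d - 1L) %/% occasion_days + 1L, n_occ)

  ## effort: active days per station-occasion
  effort <- matrix(0L, nrow(st), n_occ,
                   dimnames = list(st$station_id, NULL))
  for (s in seq_len(nrow(st))) {
    d <- seq.int(st$active_from[s], st$active_to[s])
    tab <- tabulate(occ_of_day(d), nbins = n_occ)
    effort[s, ] <- tab
  }

  y <- matrix(0L, nrow(st), n_occ, dimnames = list(st$station_id, NULL))
  ev <- survey$photos
  ev <- ev[ev$species == species, , drop = FALSE]
  if (is.null(survey$photos) || nrow(ev) == 0) {
    warn_ct("species \"%s\" has no photo events; detection matrix is all zero",
            species)
  } else {
    si <- match(ev$station_id, st$station_id)
    oi <- occ_of_day(ev$day)
    y[cbind(si, oi)] <- 1L
  }
  y[effort == 0L] <- NA_integer_
  structure(list(species = species, stations = st$station_id,
                 occasions = n_occ, y = y, effort = effort),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat(sprintf("Detection matrix: %s, %d stations x %d occasions, %d detections, %d missing cells\n",
              x$species, length(x$stations), x$occasions,
              sum(x$y == 1L, na.rm = TRUE), sum(is.na(x$y))))
  invisible(x)
}

#' Build per-site capture matrices for the focal predator
#'
#' Collapses individually identified capture records into, per site, a binary
#' individuals x occasions matrix `X` (1 if the individual was recorded at
#' least once during the occasion) and an individuals x stations matrix of
#' occasion-level capture counts (used as the spatial encounter data for
#' SECR). Sites are treated as independent populations; an individual
#' appearing at two sites is an error.
#'
#' @param survey a [ct_survey()] bundle with a capture table.
#' @param occasion_days days per trapping occasion; default from the config
#'   (3, i.e. 30 occasions over a 90-day window).
#' @return named list (one element per site) of class `capture_matrix`
#'   objects: `X`, `loc`, `stations` (the site's station table), `occasions`.
#' @export
build_capture_matrix <- function(survey, occasion_days = NULL) {
  stopifnot(inherits(survey, "ct_survey"))
  if (is.null(survey$captures)) stop_ct("survey bundle has no capture records")
  cfg <- survey$config
  occasion_days <- as.integer(occasion_days %||% cfg$cap_occasion_days)
  n_occ <- as.integer(ceiling(cfg$survey_days / occasion_days))
  caps <- survey$captures
  sites_by_ind <- tapply(caps$site, caps$individual_id,
                         function(s) length(unique(s)))
  if (any(sites_by_ind > 1))
    stop_ct("individual(s) captured at more than one site: %s (sites are modeled independently)",
            toString(names(sites_by_ind)[sites_by_ind > 1]))
  occ_of_day <- function(d) pmin((d - 1L) %/% occasion_days + 1L, n_occ)
  caps$occ <- occ_of_day(caps$day)
  out <- list()
  for (site in sort(unique(caps$site))) {
    cs <- caps[caps$site == site, , drop = FALSE]
    ids <- sort(unique(cs$individual_id))
    st <- survey$stations[survey$stations$site == site, , drop = FALSE]
    X <- matrix(0L, length(ids), n_occ, dimnames = list(ids, NULL))
    X[cbind(match(cs$individual_id, ids), cs$occ)] <- 1L
    ## occasion-level counts per trap: multiple records of an individual at
    ## the same trap within one occasion collapse to a single encounter
    key <- !duplicated(cs[c("individual_id", "station_id", "occ")])
    cu <- cs[key, , drop = FALSE]
    loc <- matrix(0L, length(ids), nrow(st),
                  dimnames = list(ids, st$station_id))
    for (r in seq_len(nrow(cu)))
      loc[cu$individual_id[r], cu$station_id[r]] <-
        loc[cu$individual_id[r], cu$station_id[r]] + 1L
    out[[site]] <- structure(list(site = site, X = X, loc = loc,
                                  stations = st, occasions = n_occ),
                             class = "capture_matrix")
  }
  out
}

#' @export
print.capture_matrix <- function(x, ...) {
  cat(sprintf("Capture matrix (%s): %d individuals x %d occasions, %d captures\n",
              x$site, nrow(x$X), x$occasions, sum(x$loc)))
  invisible(x)
}
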