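#' Survey run configuration
#'
#' Central container for the tunable constants of the pipeline. Defaults match
#' the standard design: a 90-day survey split into 9 ten-day occasions for
#' occupancy and 30 three-day occasions for capture-recapture, a 1-hour photo
#' independence window, a 15-km state-space buffer with one potential activity
#' center per km2, data augmentation at 30x the observed individuals, MCMC
#' with 50% burn-in and thinning 10, and 1000 Bayesian-bootstrap draws.
#'
#' @param survey_days length of the survey window in days.
#' @param start_date first survey day (ISO date string or `Date`); photo
#'   timestamps and capture dates are converted to 1-based survey days
#'   relative to this date.
#' @param occ_occasion_days days per occupancy trapping occasion.
#' @param cap_occasion_days days per capture-recapture trapping occasion.
#' @param independence_hours minimum separation (hours) between independent
#'   photo events of the same species at a station.
#' @param buffer_km state-space buffer width around the trap array (km).
#' @param centers_per_km2 density of potential activity centers in the state
#'   space.
#' @param aug_multiplier data-augmentation multiplier: `M = multiplier * n`
#'   observed individuals (conventionally 20-40).
#' @param n_iter MCMC iterations; @param burnin_frac burn-in fraction;
#'   @param thin thinning rate.
#' @param n_boot Bayesian bootstrap draws.
#' @param seed master seed; stages derive substreams via [derive_seed()].
#' @return an object of class `ct_config`.
#' @export
ct_config <- function(survey_days = 90, start_date = "2012-06-01",
                      occ_occasion_days = 10, cap_occasion_days = 3,
                      independence_hours = 1, buffer_km = 15,
                      centers_per_km2 = 1, aug_multiplier = 30,
                      n_iter = 50000, burnin_frac = 0.5, thin = 10,
                      n_boot = 1000, seed = 1) {
  cfg <- list(survey_days = as.integer(survey_days),
              start_date = as.Date(start_date),
              occ_occasion_days = as.integer(occ_occasion_days),
              cap_occasion_days = as.integer(cap_occasion_days),
              independence_hours = independence_hours,
              buffer_km = buffer_km, centers_per_km2 = centers_per_km2,
              aug_multiplier = aug_multiplier, n_iter = as.integer(n_iter),
              burnin_frac = burnin_frac, thin = as.integer(thin),
              n_boot = as.integer(n_boot), seed = as.integer(seed))
  with(cfg, {
    stopifnot(survey_days > 0, occ_occasion_days > 0, cap_occasion_days > 0,
              independence_hours > 0, buffer_km >= 0, centers_per_km2 > 0,
              aug_multiplier > 0, n_iter > 0, thin > 0, n_boot > 0)
    if (burnin_frac <= 0 || burnin_frac >= 1)
      stop_ct("burnin_frac must lie strictly between 0 and 1")
  })
  structure(cfg, class = "ct_config")
}

## 1-based survey day of a timestamp / date
survey_day <- function(when, start_date) {
  if (inherits(when, "POSIXct")) {
    as.integer(floor(as.numeric(difftime(when, as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC"),
                                         units = "days"))) + 1L)
  } else {
    as.integer(as.Date(when) - as.Date(start_date)) + 1L
  }
}

parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  out
}

#' Assemble and validate a survey bundle
#'
#' Cross-validates the four standard tables of a camera-trap survey and
#' returns a typed bundle used by every downstream stage.
#'
#' @param stations data frame with columns `station_id`, `site`, `x_km`,
#'   `y_km`, `dist_road_km`, `dist_river_km`, `dist_settlement_km`, `habitat`
#'   (0 = ridge, 1 = valley), `cam_spacing_m`, `active_from`, `active_to`
#'   (1-based survey days, closed interval).
#' @param photos data frame with `station_id`, `species`, `timestamp`
#'   (ISO-8601, minute resolution), `count` (individuals in frame, >= 1).
#' @param captures optional data frame of individually identified predator
#'   captures: `individual_id`, `station_id`, `date`, `site`.
#' @param masses optional data frame `species`, `mass_kg` of mean adult body
#'   masses.
#' @param config a [ct_config()].
#' @param quiet suppress the summary message.
#' @return an object of class `ct_survey`: list with the validated tables
#'   (photos gain a `day` column, captures a `day` column) and the config.
#' @export
ct_survey <- function(stations, photos = NULL, captures = NULL, masses = NULL,
                      config = ct_config(), quiet = FALSE) {
  stations <- as.data.frame(stations)
  need <- c("station_id", "site", "x_km", "y_km", "dist_road_km",
            "dist_river_km", "dist_settlement_km", "habitat", "cam_spacing_m",
            "active_from", "active_to")
  miss <- setdiff(need, names(stations))
  if (length(miss)) stop_ct("stations table lacks columns: %s", toString(miss))
  stations$station_id <- as.character(stations$station_id)
  stations$site <- as.character(stations$site)
  if (anyDuplicated(stations$station_id))
    stop_ct("duplicate station_id: %s",
            toString(unique(stations$station_id[duplicated(stations$station_id)])))
  if (!all(is.finite(stations$x_km)) || !all(is.finite(stations$y_km)))
    stop_ct("non-finite station coordinates")
  dcols <- c("dist_road_km", "dist_river_km", "dist_settlement_km")
  if (any(as.matrix(stations[dcols]) < 0, na.rm = TRUE) ||
      anyNA(stations[dcols]))
    stop_ct("distances to road/river/settlement must be finite and >= 0")
  if (!all(stations$habitat %in% c(0, 1)))
    stop_ct("habitat must be binary (0 = ridge, 1 = valley)")
  if (any(stations$cam_spacing_m <= 0)) stop_ct("cam_spacing_m must be > 0")
  if (any(stations$active_from < 1) ||
      any(stations$active_to > config$survey_days) ||
      any(stations$active_from > stations$active_to))
    stop_ct("activity window must satisfy 1 <= active_from <= active_to <= %d",
            config$survey_days)

  if (!is.null(photos)) {
    photos <- as.data.frame(photos)
    needp <- c("station_id", "species", "timestamp", "count")
    miss <- setdiff(needp, names(photos))
    if (length(miss)) stop_ct("photos table lacks columns: %s", toString(miss))
    photos$station_id <- as.character(photos$station_id)
    photos$species <- as.character(photos$species)
    bad <- which(!(photos$station_id %in% stations$station_id))
    if (length(bad))
      stop_ct("photo row %d references unknown station \"%s\"",
              bad[1], photos$station_id[bad[1]])
    photos$timestamp <- parse_timestamp(photos$timestamp)
    if (anyNA(photos$timestamp)) stop_ct("unparseable photo timestamps")
    if (any(photos$count < 1) || any(photos$count != round(photos$count)))
      stop_ct("photo count must be an integer >= 1")
    photos$day <- survey_day(photos$timestamp, config$start_date)
    idx <- match(photos$station_id, stations$station_id)
    out <- photos$day < stations$active_from[idx] |
      photos$day > stations$active_to[idx]
    if (any(out))
      stop_ct("photo row %d (station %s, day %d) falls outside the station's active window",
              which(out)[1], photos$station_id[which(out)[1]],
              photos$day[which(out)[1]])
    ## non-monotone timestamps within a station are legal but worth flagging
    if (!quiet && any(unlist(tapply(as.numeric(photos$timestamp),
                                    photos$station_id, is.unsorted))))
      message("note: photo timestamps are not monotone within stations")
  }

  if (!is.null(masses)) {
    masses <- as.data.frame(masses)
    miss <- setdiff(c("species", "mass_kg"), names(masses))
    if (length(miss)) stop_ct("masses table lacks columns: %s", toString(miss))
    masses$species <- as.character(masses$species)
    if (any(masses$mass_kg <= 0)) stop_ct("species masses must be > 0")
    if (anyDuplicated(masses$species))
      stop_ct("duplicate species in mass table")
    if (!is.null(photos) && !quiet) {
      lack <- setdiff(unique(photos$species), masses$species)
      if (length(lack))
        message("note: no mass recorded for photographed species: ",
                toString(lack))
    }
  }

  if (!is.null(captures)) {
    captures <- as.data.frame(captures)
    needc <- c("individual_id", "station_id", "date")
    miss <- setdiff(needc, names(captures))
    if (length(miss)) stop_ct("captures table lacks columns: %s", toString(miss))
    captures$individual_id <- as.character(captures$individual_id)
    captures$station_id <- as.character(captures$station_id)
    bad <- which(!(captures$station_id %in% stations$station_id))
    if (length(bad))
      stop_ct("capture row %d references unknown station \"%s\"",
              bad[1], captures$station_id[bad[1]])
    captures$day <- survey_day(captures$date, config$start_date)
    if (any(captures$day < 1) || any(captures$day > config$survey_days))
      stop_ct("capture dates must fall within the %d-day survey window",
              config$survey_days)
    st_site <- stations$site[match(captures$station_id, stations$station_id)]
    if (is.null(captures$site)) {
      captures$site <- st_site
    } else if (any(as.character(captures$site) != st_site)) {
      stop_ct("capture row %d: site does not match the station's site",
              which(as.character(captures$site) != st_site)[1])
    }
  }

  out <- structure(list(stations = stations, photos = photos,
                        captures = captures, masses = masses,
                        config = config),
                   class = "ct_survey")
  if (!quiet) {
    message(sprintf(
      "survey bundle: %d stations in %d site(s); %d photo rows; %d captures of %d individuals",
      nrow(stations), length(unique(stations$site)),
      if (is.null(photos)) 0L else nrow(photos),
      if (is.null(captures)) 0L else nrow(captures),
      if (is.null(captures)) 0L else length(unique(captures$individual_id))))
  }
  out
}

#' @export
print.ct_survey <- function(x, ...) {
  cat("Camera-trap survey bundle\n")
  cat(sprintf("  %d stations in %d site(s): %s\n", nrow(x$stations),
              length(unique(x$stations$site)),
              toString(unique(x$stations$site))))
  cat(sprintf("  survey window: %d days from %s\n", x$config$survey_days,
              format(x$config$start_date)))
  if (!is.null(x$photos))
    cat(sprintf("  %d photo rows, %d species\n", nrow(x$photos),
                length(unique(x$photos$species))))
  if (!is.null(x$captures))
    cat(sprintf("  %d captures of %d individuals\n", nrow(x$captures),
                length(unique(x$captures$individual_id))))
  invisible(x)
}

read_table_auto <- function(path) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    as.data.frame(readxl::read_excel(path))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Read a survey bundle from files
#'
#' Reads the four standard tables (CSV, or XLSX for deposited spreadsheets)
#' and validates them into a [ct_survey()] bundle.
#'
#' @param stations,photos,captures,masses file paths (CSV or XLSX); `photos`,
#'   `captures` and `masses` are optional.
#' @param config a [ct_config()].
#' @param quiet suppress the summary message.
#' @return a `ct_survey` bundle.
#' @export
read_survey <- function(stations, photos = NULL, captures = NULL,
                        masses = NULL, config = ct_config(), quiet = FALSE) {
  rd <- function(p) if (is.null(p)) NULL else read_table_auto(p)
  ct_survey(read_table_auto(stations), rd(photos), rd(captures), rd(masses),
            config = config, quiet = quiet)
}

#' Write a survey bundle to CSV files
#'
#' Writes `stations.csv`, `photos.csv`, `captures.csv`, `masses.csv` (those
#' present) into a directory; [read_survey()] on the result round-trips the
#' bundle exactly up to text normalisation.
#'
#' @param survey a `ct_survey`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "ct_survey"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name, drop = "day") {
    df <- df[setdiff(names(df), drop)]
    if ("timestamp" %in% names(df))
      df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S")
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- c(paths, wr(survey$stations, "stations.csv"))
  if (!is.null(survey$photos)) paths <- c(paths, wr(survey$photos, "photos.csv"))
  if (!is.null(survey$captures)) paths <- c(paths, wr(survey$captures, "captures.csv"))
  if (!is.null(survey$masses)) paths <- c(paths, wr(survey$masses, "masses.csv"))
  invisible(paths)
}

#' Station-level covariates used by the occupancy models
#'
#' Returns the design covariates in their raw units: `RR` = distance to the
#' nearest road or river (km), `ST` = distance to the nearest settlement (km),
#' `H` = habitat class (0 ridge / 1 valley), `DC` = spacing between the two
#' paired cameras of the station (m).
#'
#' @param stations station table from a `ct_survey`.
#' @return data frame with `station_id`, `site`, `RR`, `ST`, `H`, `DC`.
#' @export
station_covariates <- function(stations) {
  data.frame(station_id = stations$station_id, site = stations$site,
             RR = pmin(stations$dist_road_km, stations$dist_river_km),
             ST = stations$dist_settlement_km,
             H = stations$habitat,
             DC = stations$cam_spacing_m,
             stringsAsFactors = FALSE)
}
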