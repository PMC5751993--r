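#' Default prey community for simulations
#'
#' Eight terrestrial prey species of a large Neotropical felid, with mean
#' adult body masses and logit-scale occupancy / detection coefficients that
#' emulate a hunting-accessibility gradient: occupancy increases with distance
#' to the nearest road or river (`RR`, km) and to the nearest settlement
#' (`ST`, km) for hunted species, valley habitat (`H` = 1) lowers occupancy
#' for the large rodents and the smaller brocket, and detection responds to
#' the spacing between the paired cameras (`DC`, m). Photo rates given
#' presence and mean group sizes are free simulation choices (the field data
#' record only counts per picture).
#'
#' @return data frame with one row per species: `species`, `mass_kg`,
#'   `ungulate`, `b0_psi`, `b_RR`, `b_ST`, `b_H`, `b0_p`, `b_DC`,
#'   `events_per_detection`, `group_mean`.
#' @export
default_species_params <- function() {
  data.frame(
    species = c("white-lipped peccary", "collared peccary", "lowland tapir",
                "red brocket", "brown brocket", "paca", "black agouti",
                "armadillo"),
    mass_kg = c(32, 21, 180, 30, 16, 8, 4.5, 4),
    ungulate = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    b0_psi = c(-5.73, -2.26, -0.88, 0.59, -1.38, 0.14, 1.91, 0.01),
    b_RR   = c(0, 1.63, 0, 0, 0, 0, 0, 0),
    b_ST   = c(0.77, 0.43, 0.20, 0.13, 0.13, 0.14, 0, 0.07),
    b_H    = c(0, 0, 0, 0, -1.03, -1.37, -0.82, 0),
    b0_p   = c(-2.78, -1.49, -3.13, -3.49, -1.62, -1.52, -0.52, -0.60),
    b_DC   = c(0.19, 0.10, 0.21, 0.30, 0, 0, 0, -0.09),
    events_per_detection = 1.5,
    group_mean = c(5, 2, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

#' Default site accessibility features
#'
#' Four sites ordered from least to most accessible, each a rectangular
#' survey polygon with a straight road (vertical line at `road_x`), a straight
#' navigable river (horizontal line at `river_y`) and a settlement point, all
#' in site-local km. Distances of the defaults roughly span the field ranges
#' of remote (~75 km to a road, ~12 km to a settlement) to roadside (~ a few
#' km to both) camera arrays.
#'
#' @return data frame with `site`, `road_x`, `river_y`, `settlement_x`,
#'   `settlement_y`.
#' @export
default_site_features <- function() {
  data.frame(
    site = c("Lorocachi", "Tiputini", "Keweriono", "MaxusRoad"),
    road_x = c(-70, -27, -7, -0.7),
    river_y = c(-1.5, -1, -1, -1.2),
    settlement_x = c(-3, -6, 3, 2),
    settlement_y = c(-3, -6, 3, 2),
    stringsAsFactors = FALSE)
}

#' Define a simulation scenario
#'
#' Bundles every ground-truth parameter of a synthetic camera-trap survey:
#' station layout, prey occupancy/detection coefficients, photo-event process,
#' and the predator's spatial capture-recapture truth.
#'
#' @param n_stations stations per site (23-26 in the emulated design).
#' @param extent_km polygon extent per site, `c(Lx, Ly)` km (default
#'   `c(10.2, 10.5)`, ~107 km2).
#' @param min_spacing_km minimum inter-station distance (stations sit on a
#'   jittered grid whose rows play the role of cut transects).
#' @param sites site feature table as in [default_site_features()]; the number
#'   of rows sets the number of sites.
#' @param species species parameter table as in [default_species_params()].
#' @param D predator density, individuals per 100 km2 of state space.
#' @param sigma half-normal spatial scale of predator detection, km.
#' @param lambda0 baseline per-occasion encounter rate at distance zero.
#' @param fixed_N if `TRUE` (default) the predator population is a binomial
#'   point process with exactly `N = round(D * area / 100)` activity centers;
#'   otherwise N is Poisson with that mean.
#' @param config a [ct_config()] carrying the survey window, occasion lengths,
#'   buffer and the master seed.
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_stations = 25, extent_km = c(10.2, 10.5),
                         min_spacing_km = 2, sites = default_site_features(),
                         species = default_species_params(),
                         D = 5, sigma = 2.5, lambda0 = 0.2, fixed_N = TRUE,
                         config = ct_config()) {
  stopifnot(D > 0, sigma > 0, lambda0 > 0, n_stations >= 2,
            length(extent_km) == 2, all(extent_km > 0))
  coef_cols <- c("b0_psi", "b_RR", "b_ST", "b_H", "b0_p", "b_DC")
  if (!all(is.finite(as.matrix(species[coef_cols]))))
    stop_ct("species coefficient table contains non-finite values")
  structure(list(n_stations = as.integer(n_stations), extent_km = extent_km,
                 min_spacing_km = min_spacing_km, sites = sites,
                 species = species, D = D, sigma = sigma, lambda0 = lambda0,
                 fixed_N = isTRUE(fixed_N), config = config),
            class = "sim_scenario")
}

#' Simulate camera-trap stations
#'
#' Places `n_stations` per site on a jittered rectangular grid inside each
#' site polygon (grid rows emulate survey transects with 2-3 km spacing) and
#' derives the accessibility covariates from the site's simulated road, river
#' and settlement features. Sites are offset by 100 km in global coordinates
#' so arrays never overlap.
#'
#' @param scenario a [sim_scenario()].
#' @return a station table suitable for [ct_survey()]; attribute `"local"`
#'   holds the site-local coordinates.
#' @export
sim_stations <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  cfg <- scenario$config
  n <- scenario$n_stations
  Lx <- scenario$extent_km[1]; Ly <- scenario$extent_km[2]
  nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
  sx <- Lx / nc; sy <- Ly / nr
  jit <- (min(sx, sy) - scenario$min_spacing_km) / 2
  if (jit < 0)
    stop_ct(paste("cannot place %d stations %.1f km apart in a %.1f x %.1f km",
                  "polygon; reduce the station count or spacing"),
            n, scenario$min_spacing_km, Lx, Ly)
  with_seed(derive_seed(cfg$seed, "stations"), {
    out <- lapply(seq_len(nrow(scenario$sites)), function(i) {
      ft <- scenario$sites[i, ]
      gx <- (rep(seq_len(nc), nr)[seq_len(nr * nc)] - 0.5) * sx
      gy <- (rep(seq_len(nr), each = nc)[seq_len(nr * nc)] - 0.5) * sy
      keep <- sort(sample.int(nr * nc, n))
      x <- gx[keep] + runif(n, -jit, jit)
      y <- gy[keep] + runif(n, -jit, jit)
      data.frame(
        station_id = sprintf("%s_%02d", ft$site, seq_len(n)),
        site = ft$site,
        x_km = x + (i - 1) * 100, y_km = y,
        dist_road_km = abs(x - ft$road_x),
        dist_river_km = abs(y - ft$river_y),
        dist_settlement_km = sqrt((x - ft$settlement_x)^2 +
                                    (y - ft$settlement_y)^2),
        habitat = rbinom(n, 1, 0.5),
        cam_spacing_m = round(runif(n, 6, 14), 1),
        active_from = 1L, active_to = cfg$survey_days,
        x_local = x, y_local = y,
        stringsAsFactors = FALSE)
    })
    st <- do.call(rbind, out)
    local <- st[c("station_id", "x_local", "y_local")]
    st$x_local <- st$y_local <- NULL
    attr(st, "local") <- local
    st
  })
}

## zero-truncated Poisson draws
rztpois <- function(n, lambda) {
  if (lambda <= 0) return(rep(1L, n))
  x <- rpois(n, lambda)
  while (any(x == 0L)) x[x == 0L] <- rpois(sum(x == 0L), lambda)
  x
}

#' Simulate prey photo events under the occupancy model
#'
#' For each species and station, latent presence `z ~ Bernoulli(psi)` with
#' `logit(psi) = b0 + b_RR*RR + b_ST*ST + b_H*H`; given presence, each
#' occasion records a detection with `logit(p) = b0_p + b_DC*DC`, and each
#' detected occasion is expanded into one or more time-stamped photo events
#' with zero-truncated-Poisson group sizes. Stations without presence produce
#' no events.
#'
#' @param scenario a [sim_scenario()].
#' @param stations station table from [sim_stations()].
#' @return list with `photos` (a photo-event table) and `truth` (per-species
#'   latent presence, occupancy and detection probabilities).
#' @export
sim_occupancy_detections <- function(scenario, stations) {
  cfg <- scenario$config
  covs <- station_covariates(stations)
  occ_days <- cfg$occ_occasion_days
  n_occ <- ceiling(cfg$survey_days / occ_days)
  sp <- scenario$species
  with_seed(derive_seed(cfg$seed, "occupancy"), {
    rows <- list(); truth <- list()
    for (k in seq_len(nrow(sp))) {
      s <- sp[k, ]
      psi <- invlogit(s$b0_psi + s$b_RR * covs$RR + s$b_ST * covs$ST +
                        s$b_H * covs$H)
      p <- invlogit(s$b0_p + s$b_DC * covs$DC)
      z <- rbinom(nrow(covs), 1, psi)
      det <- matrix(rbinom(nrow(covs) * n_occ, 1, rep(p, n_occ)),
                    nrow(covs), n_occ) * z
      truth[[s$species]] <- list(z = setNames(z, covs$station_id),
                                 psi = psi, p = p)
      hit <- which(det == 1L, arr.ind = TRUE)
      if (nrow(hit) == 0) next
      for (r in seq_len(nrow(hit))) {
        st_i <- hit[r, 1]; occ <- hit[r, 2]
        ne <- 1L + rpois(1, s$events_per_detection - 1)
        d0 <- (occ - 1) * occ_days
        dlen <- min(occ_days, cfg$survey_days - d0)
        day <- d0 + sample.int(dlen, ne, replace = TRUE)
        ts <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC") +
          (day - 1) * 86400 + round(runif(ne, 0, 86399))
        rows[[length(rows) + 1L]] <- data.frame(
          station_id = covs$station_id[st_i], species = s$species,
          timestamp = ts, count = rztpois(ne, s$group_mean),
          stringsAsFactors = FALSE)
      }
    }
    photos <- if (length(rows)) do.call(rbind, rows) else
      data.frame(station_id = character(0), species = character(0),
                 timestamp = as.POSIXct(character(0), tz = "UTC"),
                 count = integer(0))
    photos <- photos[order(photos$station_id, photos$species,
                           photos$timestamp), ]
    rownames(photos) <- NULL
    list(photos = photos, truth = truth)
  })
}

#' Simulate a spatial capture-recapture predator population
#'
#' Places activity centers uniformly over each site's buffered trap-array
#' rectangle at density `D` per 100 km2 and generates per-occasion Bernoulli
#' encounters at each trap with half-normal detection
#' `p = 1 - exp(-lambda0 * exp(-d^2 / (2 sigma^2)))`. Only individuals with at
#' least one capture appear in the returned records.
#'
#' @param scenario a [sim_scenario()].
#' @param stations station table from [sim_stations()].
#' @param sites character vector of sites to simulate (default: all).
#' @return list with `captures` (a capture-record table) and `truth`: per site
#'   the true `N`, center coordinates (site-local km), and the observed
#'   individuals' center indices.
#' @export
sim_scr_population <- function(scenario, stations, sites = NULL) {
  cfg <- scenario$config
  loc <- attr(stations, "local")
  if (is.null(loc))
    loc <- data.frame(station_id = stations$station_id,
                      x_local = stations$x_km, y_local = stations$y_km)
  sites <- sites %||% unique(stations$site)
  K <- ceiling(cfg$survey_days / cfg$cap_occasion_days)
  with_seed(derive_seed(cfg$seed, "scr"), {
    caps <- list(); truth <- list()
    for (site in sites) {
      st <- stations[stations$site == site, , drop = FALSE]
      xy <- loc[match(st$station_id, loc$station_id), c("x_local", "y_local")]
      b <- cfg$buffer_km
      xr <- range(xy$x_local) + c(-b, b)
      yr <- range(xy$y_local) + c(-b, b)
      area <- diff(xr) * diff(yr)
      N <- if (scenario$fixed_N) as.integer(round(scenario$D * area / 100))
           else rpois(1, scenario$D * area / 100)
      cx <- runif(N, xr[1], xr[2]); cy <- runif(N, yr[1], yr[2])
      d2 <- outer(cx, xy$x_local, "-")^2 + outer(cy, xy$y_local, "-")^2
      p <- 1 - exp(-scenario$lambda0 * exp(-d2 / (2 * scenario$sigma^2)))
      ncap <- matrix(rbinom(length(p), K, p), N)
      if (all(ncap == 0))
        warn_ct("site %s: no individuals captured under this configuration",
                site)
      obs <- which(rowSums(ncap) > 0)
      recs <- list()
      for (oi in seq_along(obs)) {
        i <- obs[oi]
        for (j in which(ncap[i, ] > 0)) {
          occs <- sort(sample.int(K, ncap[i, j]))
          day <- (occs - 1) * cfg$cap_occasion_days + 1L
          recs[[length(recs) + 1L]] <- data.frame(
            individual_id = sprintf("%s_J%02d", site, oi),
            station_id = st$station_id[j],
            date = cfg$start_date + (day - 1), site = site,
            stringsAsFactors = FALSE)
        }
      }
      if (length(recs)) caps[[site]] <- do.call(rbind, recs)
      truth[[site]] <- list(N = N, area_km2 = area, D = 100 * N / area,
                            centers = cbind(x = cx, y = cy),
                            observed_center = obs)
    }
    captures <- if (length(caps)) do.call(rbind, caps) else NULL
    if (!is.null(captures)) rownames(captures) <- NULL
    list(captures = captures, truth = truth)
  })
}

#' Simulate a complete survey with known truth
#'
#' Convenience wrapper: stations, prey photo stream, predator captures and the
#' species mass table, bundled as a validated [ct_survey()] plus the
#' ground-truth record needed for parameter-recovery checks.
#'
#' @param scenario a [sim_scenario()].
#' @return list with `survey` (a `ct_survey`) and `truth` (list with
#'   `occupancy`, `scr`, and the scenario).
#' @export
simulate_survey <- function(scenario) {
  stations <- sim_stations(scenario)
  occ <- sim_occupancy_detections(scenario, stations)
  scr <- sim_scr_population(scenario, stations)
  masses <- scenario$species[c("species", "mass_kg")]
  survey <- ct_survey(stations, occ$photos, scr$captures, masses,
                      config = scenario$config, quiet = TRUE)
  attr(survey$stations, "local") <- attr(stations, "local")
  list(survey = survey,
       truth = list(occupancy = occ$truth, scr = scr$truth,
                    scenario = scenario))
}
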