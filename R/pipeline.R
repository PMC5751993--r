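#' Occupancy analysis for one species
#'
#' Builds the detection matrix, fits the candidate model set, ranks it by
#' AICc and summarises the best model: the standard per-species occupancy
#' workflow.
#'
#' @param survey a [ct_survey()].
#' @param species species to analyse.
#' @param occasion_days days per occasion (default from config).
#' @param strict_15 use the 15-model set (see [enumerate_model_set()]).
#' @param n effective sample size for AICc (default: number of stations).
#' @return list with `ranking` (AICc table), `best` (top `occ_fit`),
#'   `site_psi` (site means for the best model), `detmat`.
#' @export
occupancy_report <- function(survey, species, occasion_days = NULL,
                             strict_15 = FALSE, n = NULL) {
  det <- build_detection_matrix(survey, species, occasion_days)
  covs <- station_covariates(survey$stations)
  fits <- lapply(enumerate_model_set(species, strict_15),
                 function(sp) tryCatch(fit_occupancy(sp, det, covs),
                                       error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  ranking <- rank_aicc(fits, n = n)
  best <- attr(ranking, "fits")[[1]]
  list(ranking = ranking, best = best,
       site_psi = site_psi(best, covs), detmat = det)
}

#' Bayesian SECR density for one site
#'
#' Convenience wrapper: capture matrix, state space over the site's stations,
#' MCMC run, and the density summary.
#'
#' @param survey a [ct_survey()] with captures.
#' @param site site name.
#' @param mode state-space envelope mode (see [build_state_space()]).
#' @param ... passed to [run_secr_mcmc()] (`n_iter`, `seed`, `escalate`, ...).
#' @return list with `fit` (`secr_fit`), `density` (from
#'   [summarize_density()]), `state_space`, `capture_matrix`.
#' @export
secr_site <- function(survey, site, mode = "rectangle", ...) {
  cm <- build_capture_matrix(survey)
  if (!site %in% names(cm)) stop_ct("no captures at site %s", site)
  cm <- cm[[site]]
  ss <- build_state_space(cm$stations, buffer = survey$config$buffer_km,
                          resolution = survey$config$centers_per_km2,
                          mode = mode)
  fit <- run_secr_mcmc(cm, ss, config = survey$config, ...)
  list(fit = fit, density = summarize_density(fit), state_space = ss,
       capture_matrix = cm)
}

#' Non-spatial density table across sites
#'
#' The classical closed-population workflow: per site, the Mh jackknife
#' abundance and closure diagnostic; MMDM pooled across all sites as the
#' buffer; the union-of-disks effective trapping area per site; and
#' `D = Nhat/ETA` with its delta-method SE.
#'
#' @param survey a [ct_survey()] with captures.
#' @param occasion_days days per capture-recapture occasion (default config).
#' @return data frame (one row per site): `site`, `n_individuals`,
#'   `n_captures`, `Nhat`, `Nhat_se`, `jack_order`, `closure_p`, `mmdm_km`,
#'   `mmdm_se`, `eta_km2`, `eta_se`, `D`, `D_se`. Attribute `"mmdm"` carries
#'   the pooled MMDM object.
#' @export
nonspatial_density_report <- function(survey, occasion_days = NULL) {
  cm <- build_capture_matrix(survey, occasion_days)
  mm <- mmdm(survey)
  rows <- lapply(names(cm), function(site) {
    x <- cm[[site]]
    jack <- jackknife_mh(x$X)
    clo <- closure_check(x$X)
    eta <- effective_trapping_area(x$stations, mm$mmdm, mm$se)
    den <- density_nonspatial(jack, eta$area_km2, eta_se = eta$se)
    data.frame(site = site, n_individuals = nrow(x$X),
               n_captures = sum(x$loc), Nhat = jack$Nhat,
               Nhat_se = jack$se, jack_order = jack$order,
               closure_p = clo$p_value, mmdm_km = mm$mmdm, mmdm_se = mm$se,
               eta_km2 = eta$area_km2, eta_se = eta$se, D = den$D,
               D_se = den$se, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mmdm") <- mm
  out
}

#' Correlations of ungulate biomass with accessibility
#'
#' Station-level ungulate biomass index against distance to settlement, road
#' and river, each with a Bayesian-bootstrap highest density interval.
#'
#' @param survey a [ct_survey()].
#' @param draws bootstrap draws; @param seed seed.
#' @return data frame with `predictor`, `r`, `hdi_lo`, `hdi_hi`.
#' @export
biomass_accessibility <- function(survey, draws = NULL, seed = NULL) {
  draws <- draws %||% survey$config$n_boot
  seed <- seed %||% derive_seed(survey$config$seed, "bayesboot")
  ev <- independence_filter(survey$photos, survey$config$independence_hours)
  bi <- biomass_index(ev, survey$masses, survey$stations, "ungulates")
  st <- survey$stations
  preds <- c(settlement = "dist_settlement_km", road = "dist_road_km",
             river = "dist_river_km")
  out <- lapply(seq_along(preds), function(i) {
    bb <- bayes_boot_correlation(st[[preds[i]]], bi$bi, draws = draws,
                                 seed = seed + i)
    data.frame(predictor = names(preds)[i], r = bb$r, hdi_lo = bb$hdi[1],
               hdi_hi = bb$hdi[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
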