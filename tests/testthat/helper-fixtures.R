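## shared fixture builders and independent oracles

make_stations <- function(n = 4, sites = "A", survey_days = 90,
                          active_from = 1, active_to = survey_days) {
  data.frame(
    station_id = sprintf("S%02d", seq_len(n)),
    site = rep_len(sites, n),
    x_km = seq_len(n) * 2.5, y_km = rep(0, n),
    dist_road_km = seq_len(n), dist_river_km = rev(seq_len(n)) / 2,
    dist_settlement_km = seq_len(n) * 1.5,
    habitat = rep_len(c(0, 1), n),
    cam_spacing_m = rep_len(c(8, 10, 12), n),
    active_from = rep_len(active_from, n),
    active_to = rep_len(active_to, n),
    stringsAsFactors = FALSE)
}

make_photos <- function(station_id, species, day, hour = 12, count = 1,
                        start_date = as.Date("2012-06-01")) {
  data.frame(station_id = station_id, species = species,
             timestamp = as.POSIXct(paste(start_date, "00:00:00"),
                                    tz = "UTC") +
               (day - 1) * 86400 + hour * 3600,
             count = count, stringsAsFactors = FALSE)
}

## exhaustive latent-state enumeration of the occupancy likelihood: sums the
## joint probability over all 2^S presence vectors (route independent of the
## per-station factorisation used by occ_loglik)
occ_loglik_enum <- function(params, spec, det, covs) {
  dz <- list(Xpsi = cbind(1, as.matrix(covs[spec$psi])),
             Xp = cbind(1, as.matrix(covs[spec$p])))
  k1 <- ncol(dz$Xpsi)
  psi <- plogis(drop(dz$Xpsi %*% params[seq_len(k1)]))
  p <- plogis(drop(dz$Xp %*% params[-seq_len(k1)]))
  S <- nrow(det$y)
  tot <- 0
  for (code in 0:(2^S - 1)) {
    z <- as.integer(intToBits(code)[seq_len(S)])
    pr <- 1
    for (s in seq_len(S)) {
      pr <- pr * (if (z[s] == 1) psi[s] else 1 - psi[s])
      for (o in seq_len(ncol(det$y))) {
        y <- det$y[s, o]
        if (is.na(y)) next
        pe <- if (z[s] == 1) p[s] else 0
        pr <- pr * (if (y == 1) pe else 1 - pe)
      }
    }
    tot <- tot + pr
  }
  log(tot)
}

## generalized-jackknife derivation of the Burnham-Overton estimators, coded
## from first principles (drop-j subsample means + bias-cancelling weights)
jackknife_oracle <- function(f, t, k) {
  S <- sum(f)
  Sbar <- function(j) S - sum(vapply(seq_len(t), function(m)
    if (f[m] == 0) 0 else f[m] * choose(t - m, j - m) / choose(t, j), 0))
  sum(vapply(0:k, function(j)
    (-1)^j * choose(k, j) * (t - j)^k / factorial(k) * Sbar(j), 0))
}

## textbook Kruskal-Wallis H with tie correction
kw_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  Rj <- tapply(r, groups, sum)
  nj <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

## a one-species scenario used by recovery checks: 100 stations across the
## four-site accessibility gradient, settlement-distance effect on occupancy
wlp_scenario <- function(seed) {
  sp <- default_species_params()[1, , drop = FALSE]  # white-lipped peccary
  sim_scenario(species = sp, config = ct_config(seed = seed))
}

## Monte-Carlo union-of-disks area (independent quadrature oracle)
mc_disk_area <- function(xy, r, n_pts = 1e6, seed = 1) {
  set.seed(seed)
  xr <- range(xy$x) + c(-r, r)
  yr <- range(xy$y) + c(-r, r)
  px <- runif(n_pts, xr[1], xr[2])
  py <- runif(n_pts, yr[1], yr[2])
  inside <- rep(FALSE, n_pts)
  for (i in seq_len(nrow(xy)))
    inside <- inside | ((px - xy$x[i])^2 + (py - xy$y[i])^2 <= r^2)
  mean(inside) * diff(xr) * diff(yr)
}
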