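#' Build a discrete SECR state space
#'
#' Lays a regular grid of potential activity centers (default one per km2)
#' over the trap-array envelope expanded by a buffer (default 15 km), so that
#' every trap lies at least the buffer width inside the state-space boundary.
#' The envelope is the convex hull of the traps (`mode = "hull"`); a
#' rectangular bounding-box mode exists for deterministic geometry in tests
#' and simulations.
#'
#' @param traps data frame or matrix of trap coordinates in km (columns
#'   `x`/`y` or `x_km`/`y_km`); at least 2 traps.
#' @param buffer buffer width, km.
#' @param resolution centers per km2 (> 0).
#' @param mode `"hull"` (buffered convex hull) or `"rectangle"` (buffered
#'   bounding box).
#' @param suitability optional habitat-suitability flags: a logical/0-1 vector
#'   over the constructed centers, or a `function(x, y)` returning them;
#'   default all suitable.
#' @return an object of class `state_space`: `centers` (data frame `x`, `y`,
#'   `suitable`), `spacing` (km), `area_km2` (suitable area), `buffer`,
#'   `resolution`, `traps`.
#' @export
build_state_space <- function(traps, buffer = 15, resolution = 1,
                              mode = c("hull", "rectangle"),
                              suitability = NULL) {
  mode <- match.arg(mode)
  if (resolution <= 0) stop_ct("resolution must be > 0")
  if (buffer < 0) stop_ct("buffer must be >= 0")
  xy <- as.data.frame(traps)
  if (all(c("x_km", "y_km") %in% names(xy)))
    xy <- data.frame(x = xy$x_km, y = xy$y_km)
  if (!all(c("x", "y") %in% names(xy))) {
    xy <- as.data.frame(as.matrix(traps))
    names(xy)[1:2] <- c("x", "y")
  }
  if (nrow(xy) < 2) stop_ct("need at least 2 traps")
  spacing <- 1 / sqrt(resolution)
  gseq <- function(r) {
    lo <- r[1] - buffer
    k <- max(1L, ceiling((r[2] + buffer - lo) / spacing - 1e-9))
    lo + (seq_len(k) - 0.5) * spacing
  }
  gx <- gseq(range(xy$x)); gy <- gseq(range(xy$y))
  centers <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  if (mode == "hull" && nrow(xy) >= 3) {
    hull <- xy[chull(xy$x, xy$y), ]
    keep <- dist_to_polygon(centers$x, centers$y, hull$x, hull$y) <=
      buffer + 1e-9
    centers <- centers[keep, , drop = FALSE]
  }
  suit <- if (is.null(suitability)) rep(TRUE, nrow(centers))
          else if (is.function(suitability))
            as.logical(suitability(centers$x, centers$y))
          else as.logical(suitability)
  if (length(suit) != nrow(centers))
    stop_ct("suitability must have one flag per center (%d)", nrow(centers))
  if (!any(suit)) stop_ct("state space has no suitable centers")
  centers$suitable <- suit
  rownames(centers) <- NULL
  structure(list(centers = centers, spacing = spacing,
                 area_km2 = sum(suit) * spacing^2, buffer = buffer,
                 resolution = resolution, mode = mode, traps = xy),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf(
    "SECR state space (%s): %d centers (%d suitable) at %.2f-km spacing; %.0f km2; buffer %.1f km\n",
    x$mode, nrow(x$centers), sum(x$centers$suitable), x$spacing, x$area_km2,
    x$buffer))
  invisible(x)
}

## minimum distance from points to a convex polygon (0 inside);
## orientation-agnostic in the vertex order
dist_to_polygon <- function(px, py, vx, vy) {
  nv <- length(vx)
  pos <- rep(TRUE, length(px)); neg <- rep(TRUE, length(px))
  dmin <- rep(Inf, length(px))
  for (k in seq_len(nv)) {
    x1 <- vx[k]; y1 <- vy[k]
    x2 <- vx[k %% nv + 1]; y2 <- vy[k %% nv + 1]
    ex <- x2 - x1; ey <- y2 - y1
    cross <- ex * (py - y1) - ey * (px - x1)
    pos <- pos & (cross >= 0)
    neg <- neg & (cross <= 0)
    t <- pmin(pmax(((px - x1) * ex + (py - y1) * ey) / (ex^2 + ey^2), 0), 1)
    d <- sqrt((px - (x1 + t * ex))^2 + (py - (y1 + t * ey))^2)
    dmin <- pmin(dmin, d)
  }
  ifelse(pos | neg, 0, dmin)
}

#' Per-occasion encounter probability
#'
#' Half-normal hazard with Bernoulli encounters:
#' `p = 1 - exp(-lambda0 * exp(-d^2 / (2 sigma^2)))`, the probability that a
#' trap at distance `d` from an individual's activity center records it during
#' one occasion.
#'
#' @param d distance(s) center-to-trap, km (>= 0).
#' @param lambda0 baseline encounter rate at distance zero (> 0).
#' @param sigma half-normal spatial scale, km (> 0).
#' @return encounter probabilities in (0, 1).
#' @export
encounter_prob <- function(d, lambda0, sigma) {
  stopifnot(all(d >= 0), lambda0 > 0, sigma > 0)
  -expm1(-lambda0 * exp(-d^2 / (2 * sigma^2)))
}

#' Bayesian SECR by data-augmented MCMC
#'
#' Fits the null spatial capture-recapture model (half-normal detection,
#' Bernoulli encounters, homogeneous density) to one site's capture data with
#' a Metropolis-within-Gibbs sampler: log-scale adaptive random walks for
#' `sigma` and `lambda0` (uniform priors on wide positive ranges), exact Gibbs
#' draws of each activity center over the discrete state space, Gibbs
#' inclusion indicators for the `M - n` augmented all-zero histories, and a
#' Beta draw for the inclusion probability `psi`. If the monitored chains
#' (`N_super`, `psi`) fail the Geweke check, the run is escalated (iterations
#' doubled, up to `max_iter`) and repeated.
#'
#' @param capt a `capture_matrix` for one site (from [build_capture_matrix()]),
#'   or a list with `loc` (individuals x traps occasion-level counts) and
#'   `occasions`.
#' @param state_space a [build_state_space()] over the same traps (suitable
#'   centers are used).
#' @param n_iter MCMC iterations (before thinning; burn-in is a fraction of
#'   this); default from `config`.
#' @param burnin_frac,thin burn-in fraction and thinning rate.
#' @param aug_multiplier data augmentation: `M = ceiling(multiplier * n)`.
#' @param sigma_prior,lambda0_prior uniform prior ranges.
#' @param seed RNG seed for the sampler.
#' @param escalate escalate iterations until the Geweke diagnostic passes for
#'   `N_super` and `psi` (|z| < 1.6); `sigma`/`lambda0` convergence is
#'   reported but does not drive escalation.
#' @param max_iter escalation cap.
#' @param config optional [ct_config()] supplying defaults.
#' @return object of class `secr_fit`: `draws` (data frame with `sigma`,
#'   `lambda0`, `psi`, `N_super`, `D`), `accept`, `geweke` (z per parameter),
#'   `converged` (per parameter), `M`, `n_obs`, `area_km2`, `n_iter`.
#' @export
run_secr_mcmc <- function(capt, state_space, n_iter = NULL,
                          burnin_frac = NULL, thin = NULL,
                          aug_multiplier = NULL,
                          sigma_prior = c(0.1, 20),
                          lambda0_prior = c(1e-4, 5),
                          seed = NULL, escalate = TRUE, max_iter = 600000,
                          config = NULL) {
  cfg <- config %||% ct_config()
  n_iter <- as.integer(n_iter %||% cfg$n_iter)
  burnin_frac <- burnin_frac %||% cfg$burnin_frac
  thin <- as.integer(thin %||% cfg$thin)
  aug_multiplier <- aug_multiplier %||% cfg$aug_multiplier
  loc <- capt$loc
  K <- capt$occasions
  stopifnot(is.matrix(loc), nrow(loc) >= 1, K >= 1)
  n <- nrow(loc)
  if (!any(rowSums(loc > 0) >= 2))
    warn_ct(paste("no individual was recaptured at a second trap: sigma is",
                  "weakly identified; interpret the posterior with caution"))
  M <- as.integer(ceiling(aug_multiplier * n))
  cen <- state_space$centers[state_space$centers$suitable, , drop = FALSE]
  tr <- state_space$traps
  if (ncol(loc) != nrow(tr))
    stop_ct("capture matrix has %d traps but state space has %d",
            ncol(loc), nrow(tr))
  d2 <- outer(cen$x, tr$x, "-")^2 + outer(cen$y, tr$y, "-")^2
  area <- state_space$area_km2

  run_once <- function(iters) {
    with_seed(seed, {
      res <- secr_mcmc_cpp(
        nij = matrix(as.integer(loc), nrow(loc)), K = as.integer(K),
        d2 = d2, M = M, n_iter = as.integer(iters),
        n_burn = as.integer(floor(burnin_frac * iters)), thin = thin,
        sigma_lo = sigma_prior[1], sigma_hi = sigma_prior[2],
        lam0_lo = lambda0_prior[1], lam0_hi = lambda0_prior[2],
        sigma_init = mean(sigma_prior) / 4,
        lam0_init = 0.1)
      draws <- as.data.frame(res$draws)
      names(draws) <- c("sigma", "lambda0", "psi", "N_super")
      draws$D <- 100 * draws$N_super / area
      gz <- vapply(draws[c("sigma", "lambda0", "psi", "N_super")],
                   function(ch) tryCatch(geweke_z(ch), error = function(e)
                     NA_real_), 0)
      list(draws = draws, accept = res$accept, geweke = gz)
    })
  }

  iters <- n_iter
  repeat {
    res <- run_once(iters)
    ok <- abs(res$geweke[c("psi", "N_super")]) < 1.6
    if (all(ok, na.rm = TRUE) || !escalate || iters >= max_iter) break
    iters <- min(2L * iters, as.integer(max_iter))
    message(sprintf("Geweke check failed for %s; escalating to %d iterations",
                    toString(names(ok)[!ok %in% TRUE]), iters))
  }
  converged <- abs(res$geweke) < 1.6
  if (!all(converged[c("psi", "N_super")], na.rm = TRUE))
    warn_ct("MCMC did not reach convergence for N_super/psi at %d iterations",
            iters)
  structure(list(draws = res$draws, accept = res$accept,
                 geweke = res$geweke, converged = converged, M = M,
                 n_obs = n, area_km2 = area, n_iter = iters, thin = thin,
                 burnin_frac = burnin_frac),
            class = "secr_fit")
}

#' @export
print.secr_fit <- function(x, ...) {
  cat(sprintf("Bayesian SECR fit: %d observed, M = %d, %d iterations (%d kept)\n",
              x$n_obs, x$M, x$n_iter, nrow(x$draws)))
  s <- sapply(x$draws, function(v) c(mean = mean(v), sd = sd(v)))
  print(round(t(s), 4))
  cat("Geweke z: ", paste(sprintf("%s %.2f", names(x$geweke), x$geweke),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Geweke convergence diagnostic
#'
#' z-statistic comparing the mean of the first `first` fraction of a chain to
#' the mean of the last `last` fraction, scaled by spectral-density-based
#' standard errors; |z| < 1.6 is taken as convergence in this pipeline.
#'
#' @param chain numeric vector of MCMC draws (length >= 100).
#' @param first,last segment fractions (defaults 0.1 and 0.5).
#' @return the z statistic (scalar).
#' @export
geweke_z <- function(chain, first = 0.1, last = 0.5) {
  stopifnot(is.numeric(chain))
  if (length(chain) < 100) stop_ct("chain too short for the Geweke diagnostic")
  if (var(chain) < .Machine$double.eps)
    stop_ct("chain is (near-)constant; diagnostic degenerate")
  unname(coda::geweke.diag(coda::mcmc(chain), frac1 = first,
                           frac2 = last)$z)
}

#' Posterior density summary
#'
#' Per-draw density is `D = N_super / suitable area x 100 km2`; reports the
#' posterior mean, SD and central 95% interval.
#'
#' @param fit a [run_secr_mcmc()] result (or any object with a `draws` data
#'   frame containing `D`).
#' @return list with `mean`, `sd`, `ci95`, `n_draws`.
#' @export
summarize_density <- function(fit) {
  d <- fit$draws$D
  if (is.null(d) || !length(d)) stop_ct("empty posterior")
  list(mean = mean(d), sd = sd(d),
       ci95 = unname(quantile(d, c(0.025, 0.975))), n_draws = length(d))
}
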