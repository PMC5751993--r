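#' Specify a single-season occupancy model
#'
#' Occupancy (`psi`) may depend on any subset of the accessibility covariates
#' `RR` (distance to nearest road or river, km), `ST` (distance to nearest
#' settlement, km) and `H` (habitat class); detection (`p`) may be constant or
#' depend on `DC` (camera spacing, m). All links are logit and covariates
#' enter untransformed.
#'
#' @param psi character subset of `c("RR","ST","H")` (empty = constant).
#' @param p character subset of `"DC"` (empty = constant).
#' @param species species the model is for (label only).
#' @return an object of class `occ_spec`.
#' @export
occ_model_spec <- function(psi = character(0), p = character(0),
                           species = "") {
  psi <- as.character(psi); p <- as.character(p)
  if (!all(psi %in% c("RR", "ST", "H")))
    stop_ct("psi covariates must be drawn from RR, ST, H")
  if (!all(p %in% "DC")) stop_ct("p covariates must be drawn from DC")
  psi <- intersect(c("RR", "ST", "H"), psi)  # canonical order, unique
  p <- unique(p)
  structure(list(psi = psi, p = p, species = species), class = "occ_spec")
}

#' @export
format.occ_spec <- function(x, ...) {
  sprintf("psi(%s)p(%s)",
          if (length(x$psi)) paste(x$psi, collapse = "+") else ".",
          if (length(x$p)) paste(x$p, collapse = "+") else ".")
}

#' @export
print.occ_spec <- function(x, ...) {
  cat(sprintf("Occupancy model %s%s\n", format(x),
              if (nzchar(x$species)) paste0(" [", x$species, "]") else ""))
  invisible(x)
}

occ_param_names <- function(spec) {
  c("psi_(Intercept)",
    if (length(spec$psi)) paste0("psi_", spec$psi),
    "p_(Intercept)",
    if (length(spec$p)) paste0("p_", spec$p))
}

## design matrices (raw covariate units) for a spec
occ_design <- function(spec, covs) {
  Xpsi <- cbind(1, as.matrix(covs[spec$psi]))
  Xp <- cbind(1, as.matrix(covs[spec$p]))
  list(Xpsi = Xpsi, Xp = Xp)
}

## per-station sufficient statistics from a detection matrix
occ_suffstats <- function(det) {
  y <- det$y
  list(ndet = rowSums(y == 1L, na.rm = TRUE),
       nocc = rowSums(!is.na(y)),
       allzero = rowSums(y == 1L, na.rm = TRUE) == 0L)
}

#' Occupancy model log-likelihood
#'
#' The zero-inflated detection-history likelihood: for station s with
#' detection history over its non-missing occasions,
#' `L_s = psi_s * prod_o p_s^y (1-p_s)^(1-y) + (1 - psi_s) * 1{no detections}`.
#' Missing occasions (zero effort) drop out of the product; a station with no
#' observed occasions contributes zero to the log-likelihood. Detection
#' probability is station-level (its `DC` covariate does not vary across
#' occasions).
#'
#' @param params numeric vector on the logit scale, ordered as
#'   `(psi intercept, psi covariates, p intercept, p covariates)`.
#' @param spec an [occ_model_spec()].
#' @param det a [build_detection_matrix()] result for the spec's species.
#' @param covs station covariates from [station_covariates()], in the same
#'   station order as `det`.
#' @param gradient if `TRUE`, attach the analytic score vector as attribute
#'   `"gradient"`.
#' @return the log-likelihood (scalar).
#' @export
occ_loglik <- function(params, spec, det, covs, gradient = FALSE) {
  if (!all(is.finite(params))) stop_ct("non-finite parameters")
  dz <- occ_design(spec, covs)
  k1 <- ncol(dz$Xpsi)
  if (length(params) != k1 + ncol(dz$Xp))
    stop_ct("expected %d parameters for model %s, got %d",
            k1 + ncol(dz$Xp), format(spec), length(params))
  ss <- occ_suffstats(det)
  psi <- invlogit(drop(dz$Xpsi %*% params[seq_len(k1)]))
  p <- invlogit(drop(dz$Xp %*% params[-seq_len(k1)]))
  obs <- ss$nocc > 0L
  ## log detection-history probability given presence
  lA <- ss$ndet * log(p) + (ss$nocc - ss$ndet) * log1p(-p)
  l1 <- log(psi) + lA
  ll_s <- ifelse(ss$allzero,
                 pmax(l1, log1p(-psi)) +
                   log1p(exp(-abs(l1 - log1p(-psi)))),  # log-sum-exp
                 l1)
  ll_s[!obs] <- 0
  ll <- sum(ll_s)
  if (gradient) {
    L <- exp(ll_s)
    A <- exp(lA)
    dpsi <- ifelse(obs, psi * (1 - psi) * (A - ss$allzero) / L, 0)
    dp <- ifelse(obs, psi * A * (ss$ndet - ss$nocc * p) / L, 0)
    attr(ll, "gradient") <- unname(c(colSums(dz$Xpsi * dpsi),
                                     colSums(dz$Xp * dp)))
  }
  ll
}

## linear map from standardized-scale to raw-scale parameters
occ_std_transform <- function(spec, covs) {
  dz <- occ_design(spec, covs)
  block <- function(X) {
    k <- ncol(X)
    m <- c(0, if (k > 1) colMeans(X[, -1, drop = FALSE]))
    s <- c(1, if (k > 1) apply(X[, -1, drop = FALSE], 2, sd))
    s[s == 0 | !is.finite(s)] <- 1
    Tm <- diag(1 / s, k)
    Tm[1, ] <- -m / s
    Tm[1, 1] <- 1
    list(Tmat = Tm, m = m, s = s)
  }
  b1 <- block(dz$Xpsi); b2 <- block(dz$Xp)
  k1 <- ncol(dz$Xpsi); k2 <- ncol(dz$Xp)
  Tm <- matrix(0, k1 + k2, k1 + k2)
  Tm[seq_len(k1), seq_len(k1)] <- b1$Tmat
  Tm[k1 + seq_len(k2), k1 + seq_len(k2)] <- b2$Tmat
  ## standardized design: X_std = (x - m)/s with intercept untouched
  covs_std <- covs
  for (v in spec$psi) covs_std[[v]] <- (covs[[v]] - mean(covs[[v]])) /
    ifelse(sd(covs[[v]]) > 0, sd(covs[[v]]), 1)
  for (v in spec$p) covs_std[[v]] <- (covs[[v]] - mean(covs[[v]])) /
    ifelse(sd(covs[[v]]) > 0, sd(covs[[v]]), 1)
  list(Tmat = Tm, covs_std = covs_std)
}

#' Fit a single-season occupancy model by maximum likelihood
#'
#' Multi-start quasi-Newton (BFGS with analytic gradient) maximisation of
#' [occ_loglik()]. Optimisation runs on internally standardized covariates for
#' numerical stability; reported coefficients and their covariance are mapped
#' back to the raw scale (km, m, 0/1), i.e. untransformed estimates. Standard
#' errors come from the inverse observed information.
#'
#' @param spec an [occ_model_spec()].
#' @param det detection matrix for the spec's species.
#' @param stations station table (or covariates from [station_covariates()]).
#' @param n_starts number of additional random starts beyond the zero and the
#'   naive-occupancy-informed start.
#' @param seed seed for the random starts.
#' @return an object of class `occ_fit`: coefficients, `se`, `vcov`,
#'   `loglik`, `K` (parameter count), `psi_hat`/`p_hat` per station,
#'   `converged` flag, `spec`, `n_stations`.
#' @export
fit_occupancy <- function(spec, det, stations, n_starts = 3, seed = NULL) {
  covs <- if (all(c("RR", "ST", "H", "DC") %in% names(stations))) stations
          else station_covariates(stations)
  stopifnot(nrow(covs) == length(det$stations))
  if (sum(det$y == 1L, na.rm = TRUE) == 0L)
    stop_ct(paste("species \"%s\" was never detected; the occupancy MLE is",
                  "degenerate (treat as naive zero rather than fitting)"),
            det$species)
  std <- occ_std_transform(spec, covs)
  nms <- occ_param_names(spec)
  npar <- length(nms)
  negll <- function(th) -occ_loglik(th, spec, det, std$covs_std)
  neggr <- function(th)
    -attr(occ_loglik(th, spec, det, std$covs_std, gradient = TRUE), "gradient")
  ss <- occ_suffstats(det)
  naive_occ <- min(max(mean(!ss$allzero[ss$nocc > 0]), 0.05), 0.95)
  naive_p <- min(max(sum(ss$ndet) / max(sum(ss$nocc[!ss$allzero]), 1), 0.05),
                 0.95)
  informed <- rep(0, npar)
  informed[1] <- logit(naive_occ)
  informed[length(spec$psi) + 2] <- logit(naive_p)
  extra <- with_seed(seed %||% 7L,
                     replicate(n_starts, rnorm(npar, 0, 1), simplify = FALSE))
  starts <- c(list(rep(0, npar), informed), extra)
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(optim(s0, negll, neggr, method = "BFGS",
                          control = list(maxit = 1000, reltol = 1e-14)),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value - 1e-9) best <- fit
  }
  if (is.null(best)) stop_ct("all optimisation starts failed for %s",
                             format(spec))
  gr <- neggr(best$par)
  converged <- best$convergence == 0 && sqrt(sum(gr^2)) < 1e-4
  H <- tryCatch(optimHess(best$par, negll, neggr), error = function(e) NULL)
  V_std <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  Tm <- std$Tmat
  theta <- drop(Tm %*% best$par)
  V <- if (!is.null(V_std)) Tm %*% V_std %*% t(Tm) else
    matrix(NA_real_, npar, npar)
  if (any(!is.finite(diag(V))) || any(diag(V) < 0)) converged <- converged && FALSE
  names(theta) <- nms
  dimnames(V) <- list(nms, nms)
  dz <- occ_design(spec, covs)
  k1 <- ncol(dz$Xpsi)
  psi_hat <- invlogit(drop(dz$Xpsi %*% theta[seq_len(k1)]))
  p_hat <- invlogit(drop(dz$Xp %*% theta[-seq_len(k1)]))
  structure(list(spec = spec, coef = theta, se = sqrt(pmax(diag(V), 0)),
                 vcov = V, loglik = -best$value, K = npar,
                 psi_hat = setNames(psi_hat, covs$station_id),
                 p_hat = setNames(p_hat, covs$station_id),
                 converged = converged, n_stations = nrow(covs),
                 sites = covs$site),
            class = "occ_fit")
}

#' @export
print.occ_fit <- function(x, ...) {
  cat(sprintf("Occupancy fit %s [%s]: logLik %.3f, K = %d%s\n",
              format(x$spec), x$spec$species, x$loglik, x$K,
              if (!x$converged) " (NOT converged)" else ""))
  print(round(cbind(estimate = x$coef, se = x$se), 4))
  invisible(x)
}

#' Enumerate the candidate occupancy model set
#'
#' All combinations of occupancy-covariate subsets of `{RR, ST, H}` with
#' detection constant or on `DC`: 8 x 2 = 16 models. The emulated study design
#' counts 15 models without stating which combination was omitted; with
#' `strict_15 = TRUE` the doubly-null model `psi(.)p(.)` is dropped (one
#' plausible reading, documented as such), otherwise all 16 are returned.
#'
#' @param species species label attached to each spec.
#' @param strict_15 drop the doubly-null model to match a 15-model set.
#' @return list of [occ_model_spec()] objects.
#' @export
enumerate_model_set <- function(species = "", strict_15 = FALSE) {
  vars <- c("RR", "ST", "H")
  subsets <- unlist(lapply(0:3, function(k)
    combn(vars, k, simplify = FALSE)), recursive = FALSE)
  specs <- list()
  for (ps in subsets)
    for (pc in list(character(0), "DC"))
      specs[[length(specs) + 1L]] <- occ_model_spec(ps, pc, species)
  if (strict_15)
    specs <- Filter(function(s) length(s$psi) + length(s$p) > 0, specs)
  specs
}

#' Akaike information criterion corrected for small samples
#'
#' `AICc = -2 logLik + 2K + 2K(K+1)/(n - K - 1)`.
#'
#' @param loglik maximized log-likelihood; @param K parameter count;
#'   @param n effective sample size.
#' @return the AICc value.
#' @export
aicc <- function(loglik, K, n) {
  if (n <= K + 1) stop_ct("AICc undefined: n = %g <= K + 1 = %d", n, K + 1)
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Rank occupancy fits by AICc
#'
#' Non-converged fits are excluded (with a message). The effective sample size
#' defaults to the number of stations, the conventional choice for
#' single-season occupancy. Ties in AICc are broken by smaller `K`, then by
#' model label.
#'
#' @param fits list of [fit_occupancy()] results for one species.
#' @param n effective sample size (default: stations of the first fit).
#' @return data frame with `model`, `K`, `logLik`, `AICc`, `dAICc`, `weight`,
#'   sorted ascending in AICc; attribute `"fits"` holds the ranked fit objects.
#' @export
rank_aicc <- function(fits, n = NULL) {
  stopifnot(length(fits) >= 1)
  n <- n %||% fits[[1]]$n_stations
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv))
    message(sprintf("excluding %d non-converged model(s): %s", sum(!conv),
                    toString(vapply(fits[!conv], function(f) format(f$spec),
                                    ""))))
  fits <- fits[conv]
  if (!length(fits)) stop_ct("no converged fits to rank")
  tab <- data.frame(
    model = vapply(fits, function(f) format(f$spec), ""),
    K = as.integer(vapply(fits, function(f) f$K, 0)),
    logLik = vapply(fits, function(f) f$loglik, 0),
    stringsAsFactors = FALSE)
  tab$AICc <- mapply(aicc, tab$logLik, tab$K, MoreArgs = list(n = n))
  ord <- order(tab$AICc, tab$K, tab$model)
  tab <- tab[ord, ]
  fits <- fits[ord]
  tab$dAICc <- tab$AICc - tab$AICc[1]
  w <- exp(-0.5 * tab$dAICc)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Site-level mean occupancy with delta-method uncertainty
#'
#' Averages the station-level (unconditional, covariate-predicted) occupancy
#' estimates within each site; the standard error propagates the coefficient
#' covariance through the mean by the delta method.
#'
#' @param fit a converged [fit_occupancy()].
#' @param stations station table defining site membership (same order as the
#'   fit's stations).
#' @return data frame with `site`, `n_stations`, `psi`, `se`.
#' @export
site_psi <- function(fit, stations) {
  if (!isTRUE(fit$converged)) stop_ct("fit has not converged")
  covs <- if (all(c("RR", "ST", "H", "DC") %in% names(stations))) stations
          else station_covariates(stations)
  dz <- occ_design(fit$spec, covs)
  k1 <- ncol(dz$Xpsi)
  psi <- invlogit(drop(dz$Xpsi %*% fit$coef[seq_len(k1)]))
  out <- lapply(unique(covs$site), function(s) {
    idx <- which(covs$site == s)
    if (!length(idx)) {
      warn_ct("site %s has no stations; omitted", s)
      return(NULL)
    }
    g <- rep(0, fit$K)
    g[seq_len(k1)] <- colSums(dz$Xpsi[idx, , drop = FALSE] *
                                (psi[idx] * (1 - psi[idx]))) / length(idx)
    se <- sqrt(max(drop(t(g) %*% fit$vcov %*% g), 0))
    data.frame(site = s, n_stations = length(idx), psi = mean(psi[idx]),
               se = se, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
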