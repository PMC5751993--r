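## a tiny detection-matrix object without going through the photo pipeline
raw_detmat <- function(y, species = "sp") {
  structure(list(species = species,
                 stations = sprintf("S%02d", seq_len(nrow(y))),
                 occasions = ncol(y), y = y,
                 effort = matrix(ifelse(is.na(y), 0L, 1L), nrow(y))),
            class = "detection_matrix")
}

flat_covs <- function(n) {
  data.frame(station_id = sprintf("S%02d", seq_len(n)), site = "A",
             RR = rep(0, n), ST = rep(0, n), H = rep(0, n), DC = rep(0, n))
}

test_that("the likelihood reproduces hand-computed detection histories", {
  covs <- flat_covs(1)
  spec <- occ_model_spec()  # psi(.)p(.)
  ## psi = p = 0.5 corresponds to zero logits
  ll00 <- occ_loglik(c(0, 0), spec, raw_detmat(matrix(c(0L, 0L), 1)), covs)
  expect_equal(ll00, log(0.5 * 0.25 + 0.5), tolerance = 1e-12)
  expect_equal(ll00, -0.4700, tolerance = 1e-4)
  ll10 <- occ_loglik(c(0, 0), spec, raw_detmat(matrix(c(1L, 0L), 1)), covs)
  expect_equal(ll10, log(0.125), tolerance = 1e-12)
  ## all-missing station contributes nothing
  llna <- occ_loglik(c(0, 0), spec,
                     raw_detmat(matrix(NA_integer_, 1, 2)), covs)
  expect_equal(llna, 0)
  expect_error(occ_loglik(c(NA, 0), spec, raw_detmat(matrix(0L, 1, 2)), covs),
               "finite")
})

test_that("likelihood and score agree with exhaustive latent-state enumeration", {
  set.seed(404)
  for (rep in 1:200) {
    S <- sample(2:6, 1); O <- sample(2:4, 1)
    covs <- data.frame(station_id = sprintf("S%02d", 1:S), site = "A",
                       RR = runif(S, 0, 8), ST = runif(S, 0, 16),
                       H = rbinom(S, 1, 0.5), DC = runif(S, 6, 14))
    spec <- occ_model_spec(sample(c("RR", "ST", "H"), sample(0:3, 1)),
                           if (runif(1) < 0.5) "DC" else character(0))
    npar <- 2 + length(spec$psi) + length(spec$p)
    th <- rnorm(npar, 0, 0.3)
    y <- matrix(rbinom(S * O, 1, 0.4), S, O)
    y[runif(S * O) < 0.15] <- NA_integer_
    det <- raw_detmat(y)
    ll <- occ_loglik(th, spec, det, covs, gradient = TRUE)
    expect_equal(as.numeric(ll), occ_loglik_enum(th, spec, det, covs),
                 tolerance = 1e-10)
    ## analytic score vs central differences
    g_num <- vapply(seq_len(npar), function(k) {
      e <- rep(0, npar); e[k] <- 1e-6
      (occ_loglik(th + e, spec, det, covs) -
         occ_loglik(th - e, spec, det, covs)) / 2e-6
    }, 0)
    expect_equal(attr(ll, "gradient"), g_num, tolerance = 1e-5)
  }
})

test_that("the covariate-free MLE matches a grid-search oracle", {
  set.seed(11)
  y <- matrix(rbinom(40 * 6, 1, 0.35 * rbinom(40, 1, 0.7)), 40, 6)
  keep <- rowSums(y) >= 0
  det <- raw_detmat(y)
  covs <- flat_covs(40)
  fit <- fit_occupancy(occ_model_spec(), det, covs)
  gr <- expand.grid(psi = seq(0.01, 0.99, by = 0.005),
                    p = seq(0.01, 0.99, by = 0.005))
  lls <- mapply(function(psi, p)
    occ_loglik(c(qlogis(psi), qlogis(p)), occ_model_spec(), det, covs),
    gr$psi, gr$p)
  best <- gr[which.max(lls), ]
  expect_gte(fit$loglik, max(lls) - 1e-9)
  ## the MLE sits within one grid step of the grid optimum
  expect_lt(abs(plogis(fit$coef[["psi_(Intercept)"]]) - best$psi), 0.005)
  expect_lt(abs(plogis(fit$coef[["p_(Intercept)"]]) - best$p), 0.005)
  ## zero-detection data are refused with advice, not fitted
  expect_error(fit_occupancy(occ_model_spec(), raw_detmat(matrix(0L, 5, 4)),
                             flat_covs(5)), "never detected")
})

test_that("fits recover simulated covariate effects", {
  scen <- wlp_scenario(77)
  st <- sim_stations(scen)
  occ <- sim_occupancy_detections(scen, st)
  sv <- ct_survey(st, occ$photos, config = scen$config, quiet = TRUE)
  det <- build_detection_matrix(sv, scen$species$species[1])
  covs <- station_covariates(st)
  fit <- fit_occupancy(occ_model_spec("ST", "DC"), det, covs)
  expect_true(fit$converged)
  expect_lt(abs(fit$coef[["psi_ST"]] - 0.77), 4 * fit$se[["psi_ST"]])
  expect_lt(abs(fit$coef[["p_DC"]] - 0.19), 4 * fit$se[["p_DC"]])
  expect_true(all(fit$psi_hat > 0 & fit$psi_hat < 1))
  ## adding a covariate never lowers the maximized log-likelihood
  ll_seq <- c(fit_occupancy(occ_model_spec(), det, covs)$loglik,
              fit_occupancy(occ_model_spec("ST"), det, covs)$loglik,
              fit_occupancy(occ_model_spec(c("ST", "H")), det, covs)$loglik,
              fit_occupancy(occ_model_spec(c("RR", "ST", "H")), det,
                            covs)$loglik)
  expect_true(all(diff(ll_seq) > -1e-6))
})

test_that("the candidate model set enumerates 16 (or a strict 15) unique specs", {
  specs <- enumerate_model_set("paca")
  expect_length(specs, 16)
  labels <- vapply(specs, format, "")
  expect_identical(anyDuplicated(labels), 0L)
  expect_length(enumerate_model_set("paca", strict_15 = TRUE), 15)
  expect_identical(vapply(specs, function(s) s$species, ""),
                   rep("paca", 16))
  Ks <- vapply(specs, function(s) 2 + length(s$psi) + length(s$p), 0)
  expect_identical(sort(unique(Ks)), c(2, 3, 4, 5, 6))
})

test_that("AICc follows its formula and converges to AIC", {
  expect_equal(aicc(-10, 2, 100), 24 + 12 / 97, tolerance = 1e-12)
  expect_equal(aicc(-10, 2, 100), 24.1237, tolerance = 1e-4)
  expect_error(aicc(-10, 2, 3), "undefined")
  expect_lt(abs(aicc(-10, 2, 1e9) - 24), 1e-6)
})

test_that("model ranking orders by AICc, breaks ties by K, sums weights to 1", {
  mk_fit <- function(ll, K, label, converged = TRUE) {
    spec <- occ_model_spec(c("RR", "ST", "H")[seq_len(K - 2)],
                           species = label)
    structure(list(spec = spec, loglik = ll, K = K, converged = converged,
                   n_stations = 100), class = "occ_fit")
  }
  fits <- list(mk_fit(-10, 3, "a"), mk_fit(-10, 2, "b"),
               mk_fit(-9, 5, "c"))
  tab <- rank_aicc(fits)
  expect_identical(tab$K[1:2], c(2L, 3L))      # equal logLik: smaller K first
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_equal(tab$dAICc[1], 0)
  ## non-converged fits fall out of the ranking
  expect_message(tab2 <- rank_aicc(c(fits, list(mk_fit(-1, 2, "z", FALSE)))),
                 "non-converged")
  expect_identical(nrow(tab2), 3L)
})

test_that("site-level occupancy means and their SEs follow the delta method", {
  ## two stations engineered to psi = 0.2 and 0.6
  covs <- data.frame(station_id = c("S1", "S2"), site = "A",
                     RR = 0, ST = c(0, 1), H = 0, DC = 10)
  spec <- occ_model_spec("ST")
  beta <- c(qlogis(0.2), qlogis(0.6) - qlogis(0.2), 0)
  fit <- structure(list(spec = spec, coef = setNames(beta,
                          c("psi_(Intercept)", "psi_ST", "p_(Intercept)")),
                        vcov = diag(0, 3), K = 3, converged = TRUE,
                        n_stations = 2), class = "occ_fit")
  out <- site_psi(fit, covs)
  expect_equal(out$psi, 0.4, tolerance = 1e-12)
  expect_equal(out$se, 0)
  ## with coefficient uncertainty the SE matches a direct delta computation
  V <- matrix(c(0.04, 0.01, 0, 0.01, 0.09, 0, 0, 0, 0.02), 3)
  fit$vcov <- V
  psi <- plogis(c(beta[1], beta[1] + beta[2]))
  g <- colMeans(cbind(1, covs$ST, 0) * (psi * (1 - psi)))
  expect_equal(site_psi(fit, covs)$se, sqrt(drop(t(g) %*% V %*% g)),
               tolerance = 1e-12)
  ## constant-psi model: site means equal the common estimate
  fitc <- structure(list(spec = occ_model_spec(),
                         coef = setNames(c(qlogis(0.3), 0),
                                         c("psi_(Intercept)",
                                           "p_(Intercept)")),
                         vcov = diag(0, 2), K = 2, converged = TRUE,
                         n_stations = 2), class = "occ_fit")
  expect_equal(site_psi(fitc, covs)$psi, 0.3, tolerance = 1e-12)
  fit$converged <- FALSE
  expect_error(site_psi(fit, covs), "not converged")
})
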