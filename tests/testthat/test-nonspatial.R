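freq_to_matrix <- function(f, t) {
  ## any capture matrix with the given frequency counts
  rows <- unlist(lapply(seq_along(f), function(k) rep(k, f[k])))
  X <- matrix(0L, length(rows), t)
  for (i in seq_along(rows)) X[i, seq_len(rows[i])] <- 1L
  X
}

test_that("jackknife estimators reproduce their closed forms", {
  ## t = 10, S = 6, f1 = 3: first-order Nhat = S + f1 (t-1)/t = 8.7
  X <- freq_to_matrix(c(3, 3, rep(0, 8)), 10)
  jk <- jackknife_mh(X)
  expect_equal(jk$estimates$Nhat[1], 8.7, tolerance = 1e-12)
  expect_identical(jk$S, 6L)
  ## no singletons: first-order estimate collapses to S
  X2 <- freq_to_matrix(c(0, 4, 1, rep(0, 7)), 10)
  expect_equal(jackknife_mh(X2)$estimates$Nhat[1], 5, tolerance = 1e-12)
  ## every individual caught every time: Nhat = S, flagged
  expect_warning(jk3 <- jackknife_mh(matrix(1L, 4, 6)), "every occasion")
  expect_equal(jk3$Nhat, 4)
  expect_error(jackknife_mh(matrix(1L, 2, 1)), ">= 2 occasions")
  expect_error(jackknife_mh(rbind(c(1L, 0L), c(0L, 0L))), "all-zero")
})

test_that("per-order estimates match the generalized-jackknife derivation", {
  set.seed(606)
  for (rep in 1:300) {
    t <- sample(6:12, 1)
    f <- rpois(t, 2)
    if (sum(f) < 2) next
    jk <- jackknife_mh(freq_to_matrix(f, t))
    for (k in seq_len(nrow(jk$estimates)))
      expect_equal(jk$estimates$Nhat[k], jackknife_oracle(f, t, k),
                   tolerance = 1e-9)
  }
})

test_that("Mh abundance is recovered within its known bias on heterogeneous data", {
  set.seed(505)
  N <- 50; t <- 30
  est <- replicate(300, {
    p_i <- rbeta(N, 1.2, 8)           # individual heterogeneity, mean ~0.13
    X <- matrix(rbinom(N * t, 1, rep(p_i, t)), N, t)
    X <- X[rowSums(X) > 0, , drop = FALSE]
    jackknife_mh(X)$Nhat
  })
  expect_lt(abs(mean(est) - N) / N, 0.15)
})

test_that("the closure diagnostic is calibrated and direction-sensitive", {
  ## single capture: undefined
  out <- closure_check(matrix(c(1L, rep(0L, 9)), 1))
  expect_false(out$computable)
  expect_true(is.na(out$statistic))
  ## null calibration under closure
  set.seed(77)
  ps <- replicate(400, {
    X <- matrix(rbinom(12 * 20, 1, 0.25), 12, 20)
    X <- X[rowSums(X) > 0, , drop = FALSE]
    closure_check(X)$p_value
  })
  expect_lt(abs(mean(ps < 0.1, na.rm = TRUE) - 0.1), 0.06)
  expect_lt(abs(mean(ps, na.rm = TRUE) - 0.5), 0.06)
  ## turnover: half the animals only early, half only late -> closure rejected
  X <- matrix(0L, 10, 30)
  X[1:5, 1:5] <- matrix(rbinom(25, 1, 0.7), 5)
  X[6:10, 25:30] <- matrix(rbinom(30, 1, 0.7), 5)
  X <- X[rowSums(X) >= 2, ]
  expect_lt(closure_check(X)$p_value, 0.01)
  expect_lt(closure_check(X)$statistic, 0)
})

test_that("MMDM pools per-individual maximum movements", {
  st <- make_stations(4)
  st$x_km <- c(0, 3, 0, 8); st$y_km <- c(0, 4, 1, 0)
  caps <- data.frame(individual_id = c("a", "a", "b", "b", "c"),
                     station_id = c("S01", "S02", "S01", "S03", "S04"),
                     date = as.Date("2012-06-05"), site = "A")
  out <- mmdm(caps, st)
  expect_equal(unname(out$distances["a"]), 5)       # 3-4-5 triangle
  expect_equal(unname(out$distances["b"]), 1)
  expect_equal(out$mmdm, 3)
  expect_identical(out$n, 2L)
  expect_equal(out$se, sd(c(5, 1)) / sqrt(2))
  ## repeated captures at one station carry no movement information
  solo <- caps[caps$individual_id == "c", ][c(1, 1), ]
  expect_error(mmdm(solo, st), "cannot be estimated")
})

test_that("union-of-disks area matches geometry and Monte-Carlo quadrature", {
  one <- data.frame(x = 0, y = 0)
  eta1 <- effective_trapping_area(one, buffer_km = 6.08)
  expect_equal(eta1$area_km2, pi * 6.08^2, tolerance = 1e-4)
  expect_equal(eta1$area_km2, 116.13, tolerance = 1e-2)
  ## disjoint disks add exactly
  two <- data.frame(x = c(0, 20), y = c(0, 0))
  expect_equal(effective_trapping_area(two, 6.08)$area_km2, 2 * pi * 6.08^2,
               tolerance = 1e-4)
  ## overlapping disks: exact two-circle lens formula
  d <- 6
  r <- 5
  lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  twoover <- data.frame(x = c(0, d), y = c(0, 0))
  expect_equal(effective_trapping_area(twoover, r)$area_km2,
               2 * pi * r^2 - lens, tolerance = 1e-4)
  ## monotone in the buffer and bounded by the disjoint sum
  set.seed(3)
  xy <- data.frame(x = runif(12, 0, 10), y = runif(12, 0, 10))
  a <- vapply(c(1, 2, 4, 6), function(r)
    effective_trapping_area(xy, r)$area_km2, 0)
  expect_true(all(diff(a) > 0))
  expect_lte(a[4], 12 * pi * 36)
  ## scaling the whole geometry (coordinates and buffer) by 2 quadruples the
  ## area; with the buffer fixed, a disjoint layout's area is scale-invariant
  far <- data.frame(x = c(0, 40), y = c(0, 0))
  expect_equal(effective_trapping_area(transform(far, x = 2 * x), 12)$area_km2,
               4 * effective_trapping_area(far, 6)$area_km2,
               tolerance = 1e-6)
  expect_equal(effective_trapping_area(transform(far, x = 2 * x), 6)$area_km2,
               effective_trapping_area(far, 6)$area_km2, tolerance = 1e-6)
  ## Monte-Carlo cross-check on an irregular layout
  expect_lt(abs(effective_trapping_area(xy, 3)$area_km2 /
                  mc_disk_area(xy, 3, n_pts = 4e5, seed = 10) - 1), 0.01)
  ## buffer-perturbation SE has the half-range form
  eta <- effective_trapping_area(two, 6, se_buffer = 0.5)
  lohi <- vapply(c(5.5, 6.5), function(r)
    effective_trapping_area(two, r)$area_km2, 0)
  expect_equal(eta$se, diff(lohi) / 2, tolerance = 1e-9)
  expect_error(effective_trapping_area(two, 0), "> 0")
})

test_that("density and its delta-method SE propagate abundance and area errors", {
  den <- density_nonspatial(10, 458, nhat_se = 2, eta_se = 10)
  expect_equal(den$D, 1000 / 458, tolerance = 1e-12)
  expect_equal(den$D, 2.183, tolerance = 1e-3)
  expect_equal(den$se, den$D * sqrt((2 / 10)^2 + (10 / 458)^2),
               tolerance = 1e-12)
  expect_equal(den$se, 0.4393, tolerance = 1e-3)
  ## degenerate propagation
  expect_equal(density_nonspatial(10, 458)$se, 0)
  ## exact inverse scaling in the area
  expect_equal(density_nonspatial(10, 2 * 458)$D, den$D / 2)
  expect_error(density_nonspatial(10, 0), "> 0")
  ## jackknife objects slot straight in
  X <- freq_to_matrix(c(3, 3, rep(0, 8)), 10)
  jk <- jackknife_mh(X)
  den2 <- density_nonspatial(jk, 500)
  expect_equal(den2$D, 100 * jk$Nhat / 500)
  expect_equal(den2$Nhat_se, jk$se)
})

test_that("the site density report assembles a coherent table", {
  scen <- sim_scenario(config = ct_config(seed = 52))
  st <- sim_stations(scen)
  scr <- sim_scr_population(scen, st)
  sv <- ct_survey(st, captures = scr$captures, config = scen$config,
                  quiet = TRUE)
  tab <- nonspatial_density_report(sv)
  expect_setequal(tab$site, unique(sv$captures$site))
  expect_true(all(tab$Nhat >= tab$n_individuals))
  expect_equal(tab$D, 100 * tab$Nhat / tab$eta_km2, tolerance = 1e-9)
  expect_true(all(tab$mmdm_km == tab$mmdm_km[1]))   # pooled across sites
  expect_true(all(tab$eta_km2 > 0))
})
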