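test_that("survey bundle validates, counts, and round-trips through CSV", {
  st <- make_stations(8, sites = c("A", "A", "A", "A", "B", "B", "B", "B"))
  ph <- make_photos(c("S01", "S02", "S01"), "paca", day = c(3, 10, 40),
                    count = c(1, 2, 1))
  cap <- data.frame(individual_id = c("J1", "J1", "J2"),
                    station_id = c("S01", "S03", "S05"),
                    date = as.Date("2012-06-01") + c(4, 20, 33),
                    site = c("A", "A", "B"))
  ms <- data.frame(species = "paca", mass_kg = 8)
  sv <- ct_survey(st, ph, cap, ms, quiet = TRUE)
  expect_s3_class(sv, "ct_survey")
  expect_identical(nrow(sv$stations), 8L)
  expect_identical(length(unique(sv$captures$individual_id)), 2L)
  expect_identical(sv$photos$day, c(3L, 10L, 40L))

  dir <- withr::local_tempdir()
  write_survey(sv, dir)
  sv2 <- read_survey(file.path(dir, "stations.csv"),
                     file.path(dir, "photos.csv"),
                     file.path(dir, "captures.csv"),
                     file.path(dir, "masses.csv"), quiet = TRUE)
  for (tab in c("stations", "masses"))
    expect_equal(sv2[[tab]], sv[[tab]])
  expect_equal(sv2$photos$timestamp, sv$photos$timestamp)
  expect_equal(sv2$captures$day, sv$captures$day)
})

test_that("cross-reference and range violations are rejected with context", {
  st <- make_stations(3)
  expect_error(
    ct_survey(st, make_photos("Z9", "paca", 5), quiet = TRUE), "Z9")
  expect_error(
    ct_survey(st, captures = data.frame(individual_id = "J1",
                                        station_id = "Z9",
                                        date = as.Date("2012-06-10")),
              quiet = TRUE), "Z9")
  ## photo outside the station's active window
  st2 <- make_stations(3, active_from = 20)
  expect_error(ct_survey(st2, make_photos("S01", "paca", 5), quiet = TRUE),
               "active window")
  ## capture outside the survey window
  expect_error(
    ct_survey(st, captures = data.frame(individual_id = "J1",
                                        station_id = "S01",
                                        date = as.Date("2013-06-10")),
              quiet = TRUE), "survey window")
  st$station_id[2] <- "S01"
  expect_error(ct_survey(st, quiet = TRUE), "duplicate")
  st <- make_stations(3); st$dist_road_km[1] <- -1
  expect_error(ct_survey(st, quiet = TRUE), "road")
  ms <- data.frame(species = "paca", mass_kg = 0)
  expect_error(ct_survey(make_stations(3), masses = ms, quiet = TRUE), "> 0")
})

test_that("detection matrix maps days to occasions and effort to missingness", {
  st <- make_stations(2)
  st$active_from[2] <- 11  # station 2 silent during occasion 1
  sv <- ct_survey(st, make_photos("S01", "paca", day = 12), quiet = TRUE)
  det <- build_detection_matrix(sv, "paca")
  expect_identical(det$occasions, 9L)          # 90 days / 10
  expect_identical(unname(det$y["S01", 2]), 1L)        # day 12 -> occasion 2
  expect_identical(sum(det$y == 1L, na.rm = TRUE), 1L)
  expect_true(is.na(det$y["S02", 1]))          # zero effort -> missing
  expect_identical(unname(det$effort["S02", 1]), 0L)
  expect_identical(unname(det$effort["S02", 2]), 10L)
  ## detections never exceed cells with effort
  expect_lte(sum(det$y == 1L, na.rm = TRUE), sum(det$effort > 0))
})

test_that("detection matrix is idempotent and order-independent in events", {
  st <- make_stations(5)
  ph <- make_photos(c("S01", "S03", "S03", "S05", "S01"), "paca",
                    day = c(1, 15, 88, 45, 2), count = c(1, 3, 1, 2, 1))
  sv1 <- ct_survey(st, ph, quiet = TRUE)
  sv2 <- ct_survey(st, ph[sample(nrow(ph)), ], quiet = TRUE)
  d1 <- build_detection_matrix(sv1, "paca")
  d2 <- build_detection_matrix(sv2, "paca")
  expect_identical(d1$y, d2$y)
  expect_identical(d1$y, build_detection_matrix(sv1, "paca")$y)
  ## unknown species: all-zero with warning, not an error
  expect_warning(d0 <- build_detection_matrix(sv1, "tapir"), "no photo")
  expect_true(all(d0$y == 0L, na.rm = TRUE))
})

test_that("short final occasions are kept and flagged", {
  st <- make_stations(1)
  sv <- ct_survey(st, make_photos("S01", "paca", 90), quiet = TRUE)
  expect_message(det <- build_detection_matrix(sv, "paca",
                                               occasion_days = 7),
                 "not divisible")
  expect_identical(det$occasions, 13L)     # 12 x 7 + 6
  expect_identical(unname(det$effort[1, 13]), 6L)
  expect_identical(unname(det$y[1, 13]), 1L)
})

test_that("capture matrices collapse to occasions and keep sites separate", {
  st <- make_stations(6, sites = c(rep("A", 3), rep("B", 3)))
  cap <- data.frame(
    individual_id = c("J1", "J1", "J1", "J2", "K1"),
    station_id = c("S01", "S02", "S01", "S03", "S04"),
    date = as.Date("2012-06-01") + c(4, 4, 5, 50, 10) - 1,
    site = c("A", "A", "A", "A", "B"))
  sv <- ct_survey(st, captures = cap, quiet = TRUE)
  cm <- build_capture_matrix(sv)
  expect_identical(ncol(cm$A$X), 30L)          # 90 days / 3
  ## J1 captured twice in occasion 2 (days 4, 5) -> a single 1
  expect_identical(unname(cm$A$X["J1", 2]), 1L)
  expect_identical(sum(cm$A$X["J1", ]), 1L)
  ## but at two distinct traps within the occasion -> two trap encounters
  expect_identical(sum(cm$A$loc["J1", ]), 2L)
  expect_identical(rownames(cm$B$X), "K1")
  ## an individual at two sites is rejected
  cap2 <- rbind(cap, data.frame(individual_id = "J1", station_id = "S05",
                                date = as.Date("2012-07-01"), site = "B"))
  sv2 <- ct_survey(st, captures = cap2, quiet = TRUE)
  expect_error(build_capture_matrix(sv2), "more than one site")
})

test_that("study-scale capture tables pass through with correct totals", {
  ## 59 captures of 30 individuals split 13/6/8/3 across four sites
  per_site <- c(A = 13, B = 6, C = 8, D = 3)
  st <- make_stations(8, sites = rep(names(per_site), each = 2))
  rows <- list()
  day <- 1
  for (s in names(per_site)) {
    ids <- sprintf("%s_J%02d", s, seq_len(per_site[s]))
    n_caps <- per_site[s] + c(A = 13, B = 5, C = 7, D = 4)[s]  # 59 total
    take <- rep_len(ids, n_caps)
    rows[[s]] <- data.frame(
      individual_id = take,
      station_id = st$station_id[st$site == s][rep_len(1:2, n_caps)],
      date = as.Date("2012-06-01") + (seq_len(n_caps) * 3 + day) %% 88,
      site = s)
  }
  cap <- do.call(rbind, rows)
  expect_identical(nrow(cap), 59L)
  sv <- ct_survey(st, captures = cap, quiet = TRUE)
  expect_identical(length(unique(sv$captures$individual_id)), 30L)
  cm <- build_capture_matrix(sv)
  expect_identical(vapply(cm, function(x) nrow(x$X), 0L),
                   c(A = 13L, B = 6L, C = 8L, D = 3L))
})
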