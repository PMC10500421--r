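photos_at_minutes <- function(mins, station = "S01", group = "deer") {
  data.frame(station_id = station, group = group,
             timestamp = format(as.POSIXct("2019-06-01", tz = "UTC") +
                                  mins * 60, "%Y-%m-%dT%H:%M:%S"),
             stringsAsFactors = FALSE)
}

test_that("independence filter applies the 30-min sliding rule", {
  ev <- filter_independent(photos_at_minutes(c(0, 10, 25, 70)))
  expect_equal(nrow(ev), 2)
  expect_equal(format(ev$start_time, "%H:%M"), c("00:00", "01:10"))
  expect_equal(ev$n_photos, c(3L, 1L))

  # a gap of exactly the interval starts a new event (>= 30 min apart)
  expect_equal(nrow(filter_independent(photos_at_minutes(c(0, 30)))), 2)
  expect_equal(nrow(filter_independent(photos_at_minutes(c(0, 29.9)))), 1)

  # independence is per station and per group
  two_st <- rbind(photos_at_minutes(0, "S01"), photos_at_minutes(0, "S02"))
  expect_equal(nrow(filter_independent(two_st)), 2)
  two_grp <- rbind(photos_at_minutes(0, group = "deer"),
                   photos_at_minutes(5, group = "wolf"))
  expect_equal(nrow(filter_independent(two_grp)), 2)

  expect_error(filter_independent(photos_at_minutes(0:2) |>
    transform(timestamp = c("2019-06-01T00:00:00", "junk", "2019-06-01T01:00:00"))),
    "row 2")
})

test_that("independence filter matches the brute-force oracle and is idempotent", {
  set.seed(42)
  for (rep in 1:5) {
    photos <- random_photo_stream(200)
    prev_n <- Inf
    for (interval in c(15, 30, 60)) {
      ev <- filter_independent(photos, interval)
      expect_equal(nrow(ev), brute_force_events(photos, interval))
      # monotone non-increasing in the interval
      expect_lte(nrow(ev), prev_n)
      prev_n <- nrow(ev)
      # idempotent: filtering the events again changes nothing
      ev2 <- filter_independent(
        data.frame(station_id = ev$station_id, group = ev$group,
                   timestamp = ev$start_time, n_photos = ev$n_photos),
        interval)
      expect_equal(nrow(ev2), nrow(ev))
      expect_equal(ev2$start_time, ev$start_time)
    }
  }
})

test_that("detection rates are per 100 days and pool consistently", {
  expect_equal(detection_rate(5, 250), 2.0)
  expect_equal(detection_rate(0, 100), 0.0)
  expect_equal(detection_rate(33, 100), 33.0)
  expect_error(detection_rate(1, 0), "effort")
  # pooling identity: pooled rate is the effort-weighted mean of sub-rates
  r1 <- detection_rate(7, 120); r2 <- detection_rate(4, 80)
  expect_equal(detection_rate(11, 200), (120 * r1 + 80 * r2) / 200)
})

test_that("disturbance covariates dichotomize at inclusive thresholds", {
  expect_identical(discretize_disturbance(0.15, 0.10), 1L)
  expect_identical(discretize_disturbance(0.5, 1.0), 0L)
  expect_identical(discretize_disturbance(0.10, 0.10), 1L)
  expect_error(discretize_disturbance(NaN, 1), "finite")
})

test_that("standardization gives mean 0, sample SD 1 and rejects constants", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(standardize(c(5, 5, 5)), "constant")
  expect_error(standardize(3), "at least 2")
  set.seed(1)
  x <- rlnorm(50)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("correlation screen flags collinear pairs like forest cover vs NDVI", {
  set.seed(7)
  x <- rnorm(1000); y <- rnorm(1000)
  scr <- correlation_screen(data.frame(x = x, y = y))
  expect_lt(abs(scr$r), 0.2)
  expect_false(scr$flagged)

  scr2 <- correlation_screen(data.frame(x = x, y = x))
  expect_equal(scr2$r, 1.0)
  expect_true(scr2$flagged)

  # construct forest cover with exact r = 0.6 to NDVI at n = 400
  set.seed(8)
  ndvi <- rnorm(400); z <- rnorm(400)
  resid_z <- residuals(lm(z ~ ndvi))
  rho <- 0.6 + 1e-9  # epsilon above the cut so the inclusive flag is exercised
  forest <- rho * scale(ndvi)[, 1] + sqrt(1 - rho^2) * scale(resid_z)[, 1]
  scr3 <- correlation_screen(data.frame(ndvi = ndvi, forest = forest))
  expect_equal(scr3$r, 0.6, tolerance = 1e-6)
  expect_true(scr3$flagged)

  expect_error(correlation_screen(data.frame(a = 1:2, b = 2:1)), "3 complete")
})

test_that("species inclusion needs both total and array thresholds", {
  totals <- data.frame(
    species = rep(c("elk", "wolf", "lynx"), times = c(5, 4, 10)),
    array_id = c(1:5, 1:4, 1:10),
    n_detections = c(rep(100, 5), rep(150, 4), c(rep(50, 9), 49)))
  expect_equal(species_inclusion(totals), "elk")     # 500 across 5 arrays
  # wolf: 600 in 4 arrays -> fails array rule; lynx: 499 -> fails total rule
  expect_error(species_inclusion(transform(totals, n_detections = -1)),
               "nonnegative")
})

test_that("seasonal subset keeps April-September by station-local date", {
  ev <- data.frame(
    station_id = "S01", group = "deer",
    start_time = as.POSIXct(c("2019-04-01 00:10:00", "2019-10-15 12:00:00",
                              "2019-09-30 23:00:00"), tz = "UTC"),
    stringsAsFactors = FALSE)
  out <- seasonal_subset(ev)
  expect_equal(nrow(out), 2)
  expect_true(all(format(out$start_time, "%m") %in% c("04", "09")))
  expect_equal(nrow(seasonal_subset(ev[0, ])), 0)

  # 2019-10-01 01:00 UTC is still 30 September local at 120 degrees W
  late <- data.frame(station_id = "S01", group = "deer",
                     start_time = as.POSIXct("2019-10-01 01:00:00", tz = "UTC"))
  stations <- data.frame(station_id = "S01", longitude = -120)
  expect_equal(nrow(seasonal_subset(late, stations = stations)), 1)
  expect_equal(nrow(seasonal_subset(late)), 0)
})

test_that("covariate table is standardized, coded and array-indexed as modelled", {
  d <- sim_spatial_data(seed = 20, n_arrays = 4, stations_per_array = 30,
                        baseline = 2)
  tr <- d$truth
  sim <- simulate_dataset(tr)
  ev <- filter_independent(sim$detections)
  cov <- build_covariates(ev, sim$stations)
  for (col in c("recreation_rate_std", "camera_days_std", "ndvi_std")) {
    expect_equal(mean(cov[[col]]), 0, tolerance = 1e-12)
    expect_equal(sd(cov[[col]]), 1, tolerance = 1e-12)
  }
  expect_true(all(cov$logging_high %in% 0:1))
  expect_true(all(cov$road_high %in% 0:1))
  expect_equal(cov$logging_high,
               as.integer(sim$stations$logging_fraction >= 0.1))
  expect_equal(cov$rec_x_logging,
               cov$recreation_rate_std * cov$logging_high)
  # landscape covariate: one value per array, standardized across arrays
  land <- tapply(cov$landscape_recreation_std, cov$array_index, unique)
  expect_length(unlist(land), 4)
  expect_equal(mean(unlist(land)), 0, tolerance = 1e-12)

  sdat <- build_spatial_data(ev, sim$stations, "deer")
  expect_s3_class(sdat, "spatial_model_data")
  expect_equal(length(sdat$y), nrow(sim$stations))
  expect_equal(colnames(sdat$X),
               c("recreation", "logging", "road", "camera_days", "ndvi",
                 "rec_x_logging", "rec_x_road"))
  # y counts the focal species' events per station
  expect_equal(sum(sdat$y), sum(ev$group == "deer"))
})
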