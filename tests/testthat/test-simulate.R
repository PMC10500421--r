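test_that("station generation is seeded, sized and bounded correctly", {
  tr <- simulation_truth(seed = 1, n_arrays = 10, stations_per_array = 45)
  s1 <- generate_stations(tr)
  s2 <- generate_stations(tr)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 450)
  expect_equal(length(unique(s1$array_id)), 10)
  expect_true(all(s1$logging_fraction >= 0 & s1$logging_fraction <= 1))
  expect_true(all(s1$road_density >= 0))
  expect_true(all(s1$effort_days_season >= 1))
  expect_true(all(abs(s1$latitude) <= 90))

  tr0 <- simulation_truth(seed = 2, recreation_lognormal_sigma = 0)
  s0 <- generate_stations(tr0)
  expect_equal(length(unique(s0$recreation_rate)), 1)
  expect_equal(unique(s0$recreation_rate), exp(tr0$recreation_lognormal_mu))
})

test_that("truth constructor rejects invalid parameters", {
  expect_error(simulation_truth(beta = 1:3), "beta")
  expect_error(simulation_truth(sigma_array = -1), "sigma_array")
  expect_error(simulation_truth(dispersion = 0), "dispersion")
  expect_error(simulation_truth(n_arrays = 1), "n_arrays")
  bad_diel <- list(deer = list(mean = 0, kappa = 1, weight = 0.7))
  expect_error(simulation_truth(diel_params = bad_diel), "weights")
})

test_that("counts match NB2 closed-form moments at large n", {
  # near-Poisson limit: huge size parameter, all effects zero
  tr <- simulation_truth(beta = rep(0, 8), sigma_array = 0,
                         dispersion = 1e6, n_arrays = 10,
                         stations_per_array = 1000, seed = 3)
  st <- generate_stations(tr)
  y <- as.numeric(generate_counts(st, tr))
  expect_equal(mean(y), 1, tolerance = 0.05)
  expect_equal(var(y), mean(y), tolerance = 0.05)

  # NB2 with r = 1: variance = mean + mean^2
  tr2 <- simulation_truth(beta = rep(0, 8), sigma_array = 0, dispersion = 1,
                          n_arrays = 10, stations_per_array = 1000, seed = 4)
  st2 <- generate_stations(tr2)
  y2 <- as.numeric(generate_counts(st2, tr2))
  m <- mean(y2)
  expect_equal(var(y2), m + m^2, tolerance = 0.15)
})

test_that("a moose-like negative recreation effect is recoverable from binned means", {
  tr <- simulation_truth(beta = c(-0.49, rep(0, 7)), sigma_array = 0,
                         dispersion = 5, n_arrays = 10,
                         stations_per_array = 1000, seed = 5)
  st <- generate_stations(tr)
  y <- as.numeric(generate_counts(st, tr))
  rec <- standardize(st$recreation_rate)
  # quasi-likelihood slope is consistent for the log-linear mean whatever
  # the count dispersion; this estimator never touches the model code
  slope <- coef(glm(y ~ rec, family = poisson()))[["rec"]]
  expect_equal(slope, -0.49, tolerance = 0.05)
  # and the binned means themselves decay log-linearly in the bulk
  bins <- cut(rec, quantile(rec, seq(0.05, 0.95, 0.15)), include.lowest = TRUE)
  mean_y <- tapply(y, bins, mean)
  expect_true(all(diff(log(mean_y)) < 0))
})

test_that("count generation errors on linear-predictor overflow", {
  tr <- simulation_truth(beta = c(40, rep(0, 7)), sigma_array = 0, seed = 6)
  st <- generate_stations(tr)
  expect_error(generate_counts(st, tr), "overflow.*A0")
})

test_that("diel times follow the requested von Mises mixture", {
  tr <- simulation_truth(seed = 7)
  expect_length(generate_diel_times("S1", "deer", 0, tr), 0)
  expect_error(generate_diel_times("S1", "badger", 10, tr), "unknown diel group")

  # concentration zero: Rayleigh statistic consistent with uniformity
  tr_u <- simulation_truth(seed = 8, diel_params = list(
    flat = list(mean = 0, kappa = 0, weight = 1)))
  x <- generate_diel_times("S1", "flat", 5000, tr_u)
  expect_true(all(x >= 0 & x < 2 * pi))
  z <- 5000 * (mean(cos(x))^2 + mean(sin(x))^2)  # ~ Exp(1) under uniformity
  expect_lt(z, 4.61)  # p > 0.01

  # degenerate mixture weight: all mass at the first component
  tr_m <- simulation_truth(seed = 9, diel_params = list(
    g = list(mean = c(1.2, 4), kappa = c(5, 5), weight = c(1, 0))))
  x2 <- generate_diel_times("S2", "g", 5000, tr_m)
  expect_lt(abs(circ_mean(x2) - 1.2), 0.05)

  # reproducibility per (station, group)
  expect_identical(generate_diel_times("S2", "g", 100, tr_m),
                   generate_diel_times("S2", "g", 100, tr_m))
})

test_that("generated diel samples pass a chi-square fit against the mixture density", {
  tr <- simulation_truth(seed = 10)
  x <- generate_diel_times("S9", "deer", 5000, tr)
  brk <- seq(0, 2 * pi, length.out = 25)
  obs <- table(cut(x, brk, include.lowest = TRUE))
  dp <- tr$diel_params$deer
  mids <- (brk[-1] + brk[-25]) / 2
  dens <- dp$weight[1] * dvm_true(mids, dp$mean[1], dp$kappa[1]) +
    dp$weight[2] * dvm_true(mids, dp$mean[2], dp$kappa[2])
  p_bin <- dens * diff(brk)
  p_bin <- p_bin / sum(p_bin)
  pval <- suppressWarnings(chisq.test(as.numeric(obs), p = p_bin)$p.value)
  expect_gt(pval, 0.01)
})

test_that("full dataset simulation round-trips through CSV deterministically", {
  tr <- simulation_truth(seed = 11, n_arrays = 3, stations_per_array = 4,
                         baseline_log_rate = 2)
  sim1 <- simulate_dataset(tr)
  sim2 <- simulate_dataset(tr)
  expect_identical(sim1$detections, sim2$detections)
  expect_true(all(c("station_id", "group", "timestamp", "n_photos") %in%
                    names(sim1$detections)))
  d1 <- tempfile(); d2 <- tempfile()
  write_simulated_dataset(sim1, d1)
  write_simulated_dataset(sim2, d2)
  expect_identical(readLines(file.path(d1, "detections.csv")),
                   readLines(file.path(d2, "detections.csv")))
  expect_identical(readLines(file.path(d1, "stations.csv")),
                   readLines(file.path(d2, "stations.csv")))
  unlink(c(d1, d2), recursive = TRUE)
})
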