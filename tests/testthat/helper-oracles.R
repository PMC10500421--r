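# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# O(n^2) grouping oracle for the photograph independence rule: walks each
# (station, group) stream and starts a new event whenever the gap to the
# previous photograph is at least the interval.
brute_force_events <- function(photos, interval_minutes) {
  tt <- as.POSIXct(strptime(photos$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  stopifnot(!anyNA(tt))
  n_events <- 0L
  for (sid in unique(photos$station_id)) {
    for (grp in unique(photos$group[photos$station_id == sid])) {
      times <- sort(tt[photos$station_id == sid & photos$group == grp])
      if (length(times) == 0) next
      n_events <- n_events + 1L
      for (i in seq_along(times)[-1]) {
        gap <- as.numeric(difftime(times[i], times[i - 1], units = "mins"))
        if (gap >= interval_minutes) n_events <- n_events + 1L
      }
    }
  }
  n_events
}

# True von Mises density (no estimation involved).
dvm_true <- function(x, mu, kappa) {
  if (kappa == 0) return(rep(1 / (2 * pi), length(x)))
  exp(kappa * (cos(x - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

# Numerical-integration oracle for the overlap coefficient between two
# von Mises densities: int min(f, g) over the circle on a fine grid.
overlap_true_vm <- function(mu1, k1, mu2, k2, n_grid = 10000) {
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  mean(pmin(dvm_true(grid, mu1, k1), dvm_true(grid, mu2, k2))) * 2 * pi
}

# Circular mean direction of a sample.
circ_mean <- function(x) atan2(mean(sin(x)), mean(cos(x))) %% (2 * pi)

# Random photo stream over a few stations/groups for property tests.
random_photo_stream <- function(n, n_stations = 4, n_groups = 2,
                                horizon_min = 2000) {
  data.frame(
    station_id = sample(sprintf("S%02d", seq_len(n_stations)), n, TRUE),
    group = sample(letters[seq_len(n_groups)], n, TRUE),
    timestamp = format(as.POSIXct("2019-06-01", tz = "UTC") +
                         60 * round(runif(n, 0, horizon_min)),
                       "%Y-%m-%dT%H:%M:%S"),
    stringsAsFactors = FALSE
  )
}

# Small simulated spatial dataset ready for fit_spatial().
sim_spatial_data <- function(beta = rep(0, 8), seed = 1, n_arrays = 10,
                             stations_per_array = 40, sigma_array = 0.5,
                             dispersion = 1, baseline = 0) {
  tr <- simulation_truth(beta = beta, seed = seed, n_arrays = n_arrays,
                         stations_per_array = stations_per_array,
                         sigma_array = sigma_array, dispersion = dispersion,
                         baseline_log_rate = baseline)
  st <- generate_stations(tr)
  y <- generate_counts(st, tr)
  d <- trailuse:::sim_design(st)
  list(y = as.integer(y), X = d$X, array_index = d$array_index,
       landscape_recreation = d$landscape_recreation, truth = tr,
       stations = st)
}
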