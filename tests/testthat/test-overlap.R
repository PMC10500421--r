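test_that("von Mises KDE integrates to 1 and tracks its generating density", {
  set.seed(21)
  x <- trailuse:::rvonmises(800, 2, 3)
  f <- vm_kde(x)
  grid <- seq(0, 2 * pi, length.out = 2049)
  vals <- predict(f, grid)
  integral <- sum((vals[-1] + vals[-2049]) / 2) * (2 * pi / 2048)
  expect_equal(integral, 1, tolerance = 1e-6)

  # uniform sample: nearly flat estimate
  u <- runif(5000, 0, 2 * pi)
  fu <- vm_kde(u)
  expect_lt(max(abs(predict(fu, grid) - 1 / (2 * pi))), 0.02)

  # peaked sample: mode of the estimate near the generating mean
  v <- trailuse:::rvonmises(5000, pi, 4)
  fv <- vm_kde(v)
  fine <- seq(0, 2 * pi, length.out = 4096)
  expect_lt(abs(fine[which.max(predict(fv, fine))] - pi), 0.1)

  expect_error(vm_kde(runif(5)), "at least 10")
})

test_that("KDE falls back to the uniform density for zero concentration", {
  x <- seq(0, 2 * pi, length.out = 13)[-13]  # perfectly balanced -> Rbar = 0
  expect_warning(f <- vm_kde(x), "uniform")
  expect_true(f$uniform)
  expect_equal(predict(f, c(0, 1, 3)), rep(1 / (2 * pi), 3))
})

test_that("Dhat4 is symmetric, bounded, and exact for identical samples", {
  set.seed(22)
  for (i in 1:5) {
    s1 <- trailuse:::rvonmises(120, runif(1, 0, 2 * pi), runif(1, 0.5, 6))
    s2 <- trailuse:::rvonmises(150, runif(1, 0, 2 * pi), runif(1, 0.5, 6))
    d12 <- delta4(s1, s2)$delta4
    d21 <- delta4(s2, s1)$delta4
    expect_equal(d12, d21, tolerance = 1e-12)
    expect_gte(d12, 0)
    expect_lte(d12, 1)
  }
  s <- trailuse:::rvonmises(200, 1, 2)
  expect_identical(delta4(s, s)$delta4, 1)
})

test_that("Dhat4 approximates the true overlap of von Mises pairs", {
  # spot-check two grid cells here; the full 9-cell sweep runs in the
  # acceptance suite
  set.seed(23)
  for (cell in list(c(kappa = 2, sep = pi / 2), c(kappa = 8, sep = pi))) {
    s1 <- trailuse:::rvonmises(2000, 0, cell["kappa"])
    s2 <- trailuse:::rvonmises(2000, cell["sep"], cell["kappa"])
    est <- delta4(s1, s2)$delta4
    truth <- overlap_true_vm(0, cell["kappa"], cell["sep"], cell["kappa"])
    expect_lt(abs(est - truth), 0.05)
  }
  # identical uniforms: true overlap 1, estimator within noise
  u1 <- runif(2000, 0, 2 * pi); u2 <- runif(2000, 0, 2 * pi)
  expect_gt(delta4(u1, u2)$delta4, 0.9)
})

test_that("bootstrap interval brackets the point estimate", {
  set.seed(24)
  s1 <- trailuse:::rvonmises(60, 0, 2)
  s2 <- trailuse:::rvonmises(60, 1, 2)
  bt <- delta4_bootstrap(s1, s2, n_boot = 99)
  expect_lte(bt$ci[1], bt$estimate)
  expect_gte(bt$ci[2], bt$estimate)
  expect_length(bt$boot, 99)
})

test_that("station pair filter applies the >=25-per-group rule inclusively", {
  ev <- data.frame(
    station_id = c(rep("S1", 54), rep("S2", 50), rep("S3", 20)),
    group = c(rep("deer", 30), rep("rec", 24),    # S1: 30/24 -> out
              rep("deer", 25), rep("rec", 25),    # S2: 25/25 -> in
              rep("deer", 10), rep("rec", 10)),   # S3: out
    stringsAsFactors = FALSE)
  keep <- station_pair_filter(ev, c("deer", "rec"))
  expect_equal(as.character(keep), "S2")
  # pooled totals (65, 59) fall short of 75: the large-sample estimator is
  # not recommended
  expect_equal(attr(keep, "estimator"), "Dhat1")

  none <- station_pair_filter(ev[ev$station_id == "S3", ], c("deer", "rec"))
  expect_length(none, 0)
})

test_that("station overlaps computes Dhat4 for qualifying stations only", {
  tr <- simulation_truth(seed = 25, n_arrays = 2, stations_per_array = 6,
                         baseline_log_rate = 3.6,
                         recreation_lognormal_mu = 3.5)
  sim <- simulate_dataset(tr)
  ev <- filter_independent(sim$detections)
  ov <- station_overlaps(ev, sim$stations, c("deer", "recreation"))
  expect_true(all(ov$n1 >= 25 & ov$n2 >= 25))
  expect_true(all(ov$delta4 >= 0 & ov$delta4 <= 1))
  expect_gt(nrow(ov), 0)
  # crepuscular deer vs diurnal recreation: overlap well below 1
  expect_true(all(ov$delta4 < 0.95))
})
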