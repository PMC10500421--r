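# Synthetic multi-array camera-trap data with known generative parameters.
# The generator mirrors the two-level count model used for inference:
#   y_i  ~ NB2(mu_i = exp(eta_i), r)
#   eta_i = baseline + b1*rec_i + b2*logging_i + b3*road_i + b4*camdays_i
#           + b5*ndvi_i + b6*rec*logging_i + b7*rec*road_i + eps_{array(i)}
#   eps_j ~ Normal(b8 * landscape_rec_j, sigma_array^2)
# so that fitted models can be checked against the truth that produced the
# data.

#' Ground-truth parameters for a synthetic camera-trap survey
#'
#' Bundles every generative parameter of the synthetic multi-array survey:
#' the eight log-scale effects of the site-use model (seven local effects and
#' one landscape-scale recreation effect on the array random intercept), the
#' array-effect standard deviation, the negative-binomial size parameter, the
#' survey geometry, the log-normal distribution of local recreation rates,
#' and per-group von Mises mixtures for diel activity.
#'
#' @param beta numeric vector of 8 log-scale effects, in the order
#'   recreation, logging, road, camera-days, NDVI, recreation x logging,
#'   recreation x road, landscape recreation.
#' @param sigma_array positive SD of array random intercepts around their
#'   landscape-driven mean.
#' @param dispersion positive NB2 size parameter `r`
#'   (variance `mu + mu^2 / r`).
#' @param n_arrays number of camera arrays (>= 2).
#' @param stations_per_array stations per array (>= 2).
#' @param recreation_lognormal_mu,recreation_lognormal_sigma meanlog / sdlog
#'   of station-level recreation detection rates (per 100 days). Half of the
#'   log-scale variation is shared within an array so that landscape-scale
#'   recreation differs between arrays.
#' @param baseline_log_rate grand mean of the linear predictor; the fitted
#'   model has no fixed intercept, so a non-zero baseline is absorbed by the
#'   array effects (raising counts without touching effect recovery, because
#'   the landscape covariate is centred).
#' @param diel_params named list of von Mises mixtures (one per group, e.g.
#'   `deer`, `recreation`, `carnivore`), each a list with numeric vectors
#'   `mean` (radians), `kappa` (concentrations >= 0) and `weight`
#'   (summing to 1).
#' @param seed integer seed fixing every table the generator emits.
#' @return an object of class `sim_truth`.
#' @export
simulation_truth <- function(beta = c(recreation = 0, logging = 0, road = 0,
                                      camera_days = 0, ndvi = 0,
                                      rec_x_logging = 0, rec_x_road = 0,
                                      landscape_recreation = 0),
                             sigma_array = 0.5,
                             dispersion = 1,
                             n_arrays = 10,
                             stations_per_array = 40,
                             recreation_lognormal_mu = 1.6,
                             recreation_lognormal_sigma = 1,
                             baseline_log_rate = 0,
                             diel_params = default_diel_params(),
                             seed = 1L) {
  beta <- as.numeric(beta)
  if (length(beta) != 8 || any(!is.finite(beta)))
    stop("`beta` must be 8 finite values (7 local effects + landscape effect)")
  if (!is.finite(sigma_array) || sigma_array < 0)
    stop("`sigma_array` must be >= 0")
  if (!is.finite(dispersion) || dispersion <= 0)
    stop("`dispersion` must be > 0")
  if (n_arrays < 2) stop("`n_arrays` must be >= 2")
  if (stations_per_array < 2) stop("`stations_per_array` must be >= 2")
  if (recreation_lognormal_sigma < 0)
    stop("`recreation_lognormal_sigma` must be >= 0")
  for (g in names(diel_params)) {
    dp <- diel_params[[g]]
    if (!all(c("mean", "kappa", "weight") %in% names(dp)))
      stop("diel_params[['", g, "']] needs `mean`, `kappa`, `weight`")
    if (length(dp$mean) != length(dp$kappa) ||
        length(dp$mean) != length(dp$weight))
      stop("diel mixture components must have equal lengths for group ", g)
    if (any(dp$kappa < 0)) stop("von Mises concentrations must be >= 0")
    if (abs(sum(dp$weight) - 1) > 1e-8)
      stop("mixture weights must sum to 1 for group ", g)
  }
  names(beta) <- c("recreation", "logging", "road", "camera_days", "ndvi",
                   "rec_x_logging", "rec_x_road", "landscape_recreation")
  structure(list(beta = beta, sigma_array = sigma_array,
                 dispersion = dispersion, n_arrays = as.integer(n_arrays),
                 stations_per_array = as.integer(stations_per_array),
                 recreation_lognormal_mu = recreation_lognormal_mu,
                 recreation_lognormal_sigma = recreation_lognormal_sigma,
                 baseline_log_rate = baseline_log_rate,
                 diel_params = diel_params, seed = as.integer(seed)),
            class = "sim_truth")
}

#' Default diel activity mixtures for the three synthetic groups
#'
#' Crepuscular deer (activity peaks near sunrise and sunset, i.e. pi/2 and
#' 3*pi/2 in solar radians), diurnal recreation centred on solar noon, and
#' broadly nocturnal carnivores centred on solar midnight.
#'
#' @return named list of von Mises mixture specifications.
#' @export
default_diel_params <- function() {
  list(
    deer = list(mean = c(pi / 2, 3 * pi / 2), kappa = c(2, 2),
                weight = c(0.5, 0.5)),
    recreation = list(mean = pi, kappa = 3, weight = 1),
    carnivore = list(mean = 0, kappa = 1.2, weight = 1)
  )
}

#' Generate a synthetic station table
#'
#' Lays out `n_arrays` camera arrays across a western-Canada-like extent and
#' draws per-station effort, disturbance covariates and local recreation
#' rates. Recreation rates are log-normal with an array-level component so
#' that landscape-scale recreation varies between arrays. Forest cover is
#' generated correlated with NDVI, mimicking the collinearity that motivates
#' a correlation screen.
#'
#' @param truth a [simulation_truth()] object.
#' @return a `data.frame` with one row per station: `station_id`, `array_id`,
#'   `latitude`, `longitude`, `effort_days_season`, `effort_days_total`,
#'   `logging_fraction`, `road_density`, `ndvi`, `forest_pct`,
#'   `recreation_rate` (true detections per 100 days).
#' @export
generate_stations <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(truth$seed)
  J <- truth$n_arrays
  m <- truth$stations_per_array
  n <- J * m
  array_id <- rep(seq_len(J), each = m)
  # array centres within a BC/AB-like window, stations jittered around them
  centre_lat <- runif(J, 49, 54)
  centre_lon <- runif(J, -126, -114)
  lat <- pmin(65, pmax(-65, centre_lat[array_id] + rnorm(n, 0, 0.05)))
  lon <- centre_lon[array_id] + rnorm(n, 0, 0.08)
  effort_season <- pmax(1, round(runif(n, 60, 183)))
  effort_total <- effort_season + pmax(0, round(runif(n, 0, 150)))
  logging_fraction <- rbeta(n, 0.4, 2.5)        # mostly low, some heavily cut
  road_density <- rexp(n, rate = 1 / 0.8)       # km/km^2, some above 1
  ndvi <- runif(n, 0.35, 0.9)
  forest_pct <- pmin(100, pmax(0, 100 * (0.55 * (ndvi - 0.35) / 0.55 +
                                           rnorm(n, 0.25, 0.18))))
  sig <- truth$recreation_lognormal_sigma
  array_shift <- rnorm(J, 0, sig / sqrt(2))
  station_z <- rnorm(n, 0, sig / sqrt(2))
  recreation_rate <- exp(truth$recreation_lognormal_mu +
                           array_shift[array_id] + station_z)
  data.frame(
    station_id = sprintf("A%02d-S%03d", array_id, seq_len(n)),
    array_id = array_id,
    latitude = lat,
    longitude = lon,
    effort_days_season = effort_season,
    effort_days_total = effort_total,
    logging_fraction = logging_fraction,
    road_density = road_density,
    ndvi = ndvi,
    forest_pct = forest_pct,
    recreation_rate = recreation_rate,
    stringsAsFactors = FALSE
  )
}

# Design pieces shared by the generator and by recovery tests: standardized
# local covariates, binary disturbance indicators and the array-mean
# landscape recreation covariate, exactly as the fitted model defines them.
sim_design <- function(stations,
                       logging_threshold = 0.1,
                       road_threshold = 1) {
  rec_std <- standardize(stations$recreation_rate)
  logging <- discretize_disturbance(stations$logging_fraction, logging_threshold)
  road <- discretize_disturbance(stations$road_density, road_threshold)
  cam_std <- standardize(stations$effort_days_season)
  ndvi_std <- standardize(stations$ndvi)
  X <- cbind(recreation = rec_std,
             logging = logging,
             road = road,
             camera_days = cam_std,
             ndvi = ndvi_std,
             rec_x_logging = rec_std * logging,
             rec_x_road = rec_std * road)
  arr_means <- tapply(stations$recreation_rate, stations$array_id, mean)
  land <- standardize(as.numeric(arr_means))
  list(X = X, array_index = as.integer(stations$array_id),
       landscape_recreation = land)
}

#' Generate negative-binomial detection counts from the ground truth
#'
#' Draws one count per station from the generative side of the two-level
#' site-use model: the linear predictor combines the seven standardized /
#' binary local covariates with an array random intercept whose mean is the
#' landscape recreation effect times the array's (standardized) mean
#' recreation rate.
#'
#' @param stations station table from [generate_stations()].
#' @param truth the [simulation_truth()] that produced `stations`.
#' @return integer vector of counts, with the realised linear predictor and
#'   array effects attached as attributes `eta` and `eps`.
#' @export
generate_counts <- function(stations, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(truth$seed + 1L)
  d <- sim_design(stations)
  J <- truth$n_arrays
  eps <- rnorm(J, mean = truth$beta[["landscape_recreation"]] *
                 d$landscape_recreation,
               sd = truth$sigma_array)
  eta <- truth$baseline_log_rate +
    as.numeric(d$X %*% truth$beta[1:7]) + eps[d$array_index]
  bad <- which(abs(eta) > 30)
  if (length(bad) > 0)
    stop("linear predictor overflow (|eta| > 30) at station ",
         stations$station_id[bad[1]])
  y <- rnbinom(length(eta), mu = exp(eta), size = truth$dispersion)
  attr(y, "eta") <- eta
  attr(y, "eps") <- eps
  y
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution.
rvonmises <- function(n, mu, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r0 <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r0 * z) / (r0 + z)
    cc <- kappa * (r0 - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (sign(u[3] - 0.5) * acos(f) + mu) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Draw diel detection times from a group's von Mises mixture
#'
#' @param station a station id (any single value); combined with the group
#'   and the truth seed to derive a reproducible stream per (station, group).
#' @param group name of a mixture in `truth$diel_params`.
#' @param n number of times to draw.
#' @param truth a [simulation_truth()] object.
#' @return numeric vector of `n` radians in `[0, 2*pi)`.
#' @export
generate_diel_times <- function(station, group, n, truth) {
  stopifnot(inherits(truth, "sim_truth"), n >= 0)
  if (!group %in% names(truth$diel_params))
    stop("unknown diel group '", group, "'; available: ",
         paste(names(truth$diel_params), collapse = ", "))
  key <- sum(utf8ToInt(paste0(station, "/", group))) %% 100000L
  set.seed((truth$seed + 131L * key) %% .Machine$integer.max)
  dp <- truth$diel_params[[group]]
  if (n == 0) return(numeric(0))
  comp <- sample.int(length(dp$weight), n, replace = TRUE, prob = dp$weight)
  out <- numeric(n)
  for (k in unique(comp)) {
    idx <- comp == k
    out[idx] <- rvonmises(sum(idx), dp$mean[k], dp$kappa[k])
  }
  out
}

#' Simulate a full detection-record dataset
#'
#' Produces the two standard CSV-shaped tables the pipeline consumes: a
#' station table and a detection table with one row per independent
#' detection event (station, group, ISO timestamp). Counts for the focal
#' species come from [generate_counts()]; recreation and carnivore event
#' counts are Poisson around their station rates; each event gets a date
#' uniform over April-September and a time-of-day drawn from the group's
#' diel mixture (interpreted as clock time, a simplification the methods
#' vignette discusses).
#'
#' @param truth a [simulation_truth()] object.
#' @param species name used for the focal species' rows (default `"deer"`).
#' @param year calendar year stamped on events.
#' @param carnivore_rate mean carnivore detections per 100 days.
#' @return list with `stations`, `detections` (data.frame: `station_id`,
#'   `group`, `timestamp`, `n_photos`), `y` (focal counts) and `truth`.
#' @export
simulate_dataset <- function(truth, species = "deer", year = 2019,
                             carnivore_rate = 8) {
  stations <- generate_stations(truth)
  y <- generate_counts(stations, truth)
  set.seed(truth$seed + 2L)
  n <- nrow(stations)
  n_rec <- rpois(n, stations$recreation_rate * stations$effort_days_season / 100)
  n_car <- rpois(n, carnivore_rate * stations$effort_days_season / 100)
  season_start <- as.POSIXct(sprintf("%d-04-01 00:00:00", year), tz = "UTC")
  season_days <- 183L
  mk_events <- function(i, group, count, diel_group) {
    if (count == 0) return(NULL)
    days <- sort(sample.int(season_days, count, replace = TRUE)) - 1L
    rad <- generate_diel_times(stations$station_id[i], diel_group, count, truth)
    secs <- days * 86400 + rad / (2 * pi) * 86400
    data.frame(station_id = stations$station_id[i], group = group,
               timestamp = format(season_start + secs,
                                  "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               n_photos = 1L, stringsAsFactors = FALSE)
  }
  pieces <- vector("list", 3L * n)
  for (i in seq_len(n)) {
    pieces[[3 * i - 2]] <- mk_events(i, species, y[i], "deer")
    pieces[[3 * i - 1]] <- mk_events(i, "recreation", n_rec[i], "recreation")
    pieces[[3 * i]] <- mk_events(i, "carnivore", n_car[i], "carnivore")
  }
  detections <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  rownames(detections) <- NULL
  list(stations = stations, detections = detections, y = y, truth = truth)
}

#' Simulate station-level overlap coefficients from a Gaussian LMM truth
#'
#' Generates a response for the overlap mixed model directly from its
#' generative equation: per-station Dhat4 values equal to a linear
#' combination of covariates plus an array random intercept and Gaussian
#' residual. Used for parameter-recovery checks of [fit_overlap_lmm()].
#'
#' @param beta named numeric vector of effects; names become design columns.
#'   Binary columns (`logging`, `road`) are Bernoulli(0.4); all other
#'   covariates are standard normal (standardized detection counts/rates).
#' @param n_stations,n_arrays design size.
#' @param sigma_array,sigma_resid SDs of the array intercepts and residuals.
#' @param intercept grand mean of the response (absorbed by the array
#'   effects at fitting time, as in the count model).
#' @param seed integer seed.
#' @return list `y`, `X`, `array_index`, `truth`.
#' @export
simulate_overlap_data <- function(beta = c(logging = 0, road = 0.13,
                                           carnivore_rate = 0,
                                           n_muledeer = 0, n_recreation = 0),
                                  n_stations = 64, n_arrays = 6,
                                  sigma_array = 0.05, sigma_resid = 0.1,
                                  intercept = 0.6, seed = 1L) {
  set.seed(seed)
  array_index <- sort(rep_len(seq_len(n_arrays), n_stations))
  p <- length(beta)
  X <- matrix(0, n_stations, p, dimnames = list(NULL, names(beta)))
  for (k in seq_len(p)) {
    X[, k] <- if (names(beta)[k] %in% c("logging", "road"))
      rbinom(n_stations, 1, 0.4) else rnorm(n_stations)
  }
  eps <- rnorm(n_arrays, 0, sigma_array)
  y <- intercept + as.numeric(X %*% beta) + eps[array_index] +
    rnorm(n_stations, 0, sigma_resid)
  y <- pmin(1, pmax(0, y))
  list(y = y, X = X, array_index = array_index,
       truth = list(beta = beta, sigma_array = sigma_array,
                    sigma_resid = sigma_resid, intercept = intercept))
}

#' Write a simulated dataset to CSV plus a truth JSON
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stations = file.path(dir, "stations.csv"),
             detections = file.path(dir, "detections.csv"),
             truth = file.path(dir, "truth.json"))
  write.csv(sim$stations, paths["stations"], row.names = FALSE)
  write.csv(sim$detections, paths["detections"], row.names = FALSE)
  tr <- sim$truth
  tr$beta <- as.list(tr$beta)
  jsonlite::write_json(unclass(tr), paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
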