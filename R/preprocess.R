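# From raw photograph records to independent detection events, detection
# rates and the standardized covariate tables the models consume.

parse_timestamps <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0)
    stop("unparseable timestamp at row ", bad[1], ": '", x[bad[1]], "'")
  out
}

#' Collapse photographs into independent detection events
#'
#' Applies the standard camera-trap independence rule: consecutive
#' photographs of the same group at the same station separated by less than
#' `interval_minutes` belong to one event; a gap of at least the interval
#' (measured to the previous photograph, i.e. a sliding rule) starts a new
#' event. Events carry the first photograph's timestamp.
#'
#' @param photos data.frame with columns `station_id`, `group`, `timestamp`
#'   (POSIXct or ISO-8601 string) and optionally `n_photos`.
#' @param interval_minutes independence interval in minutes (default 30).
#' @return data.frame of events: `station_id`, `group`, `start_time`
#'   (POSIXct, UTC), `n_photos` (photographs merged into the event).
#' @export
filter_independent <- function(photos, interval_minutes = 30) {
  stopifnot(is.data.frame(photos),
            all(c("station_id", "group", "timestamp") %in% names(photos)))
  if (nrow(photos) == 0)
    return(data.frame(station_id = character(), group = character(),
                      start_time = as.POSIXct(character(), tz = "UTC"),
                      n_photos = integer(), stringsAsFactors = FALSE))
  tt <- parse_timestamps(photos$timestamp)
  np <- if ("n_photos" %in% names(photos)) photos$n_photos else rep(1L, nrow(photos))
  o <- order(photos$station_id, photos$group, tt)
  sid <- photos$station_id[o]; grp <- photos$group[o]; tt <- tt[o]; np <- np[o]
  gap <- c(Inf, as.numeric(difftime(tt[-1], tt[-length(tt)], units = "mins")))
  new_series <- c(TRUE, sid[-1] != sid[-length(sid)] | grp[-1] != grp[-length(grp)])
  new_event <- new_series | gap >= interval_minutes
  ev <- cumsum(new_event)
  first <- !duplicated(ev)
  out <- data.frame(station_id = sid[first], group = grp[first],
                    start_time = tt[first],
                    n_photos = as.integer(tapply(np, ev, sum)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Detection rate per 100 active camera days
#'
#' @param n_events number of independent events (vectorized).
#' @param effort_days active camera days over the same window; must be > 0.
#' @return numeric rate(s): `100 * n_events / effort_days`.
#' @export
detection_rate <- function(n_events, effort_days) {
  if (any(effort_days <= 0))
    stop("effort_days must be > 0; exclude zero-effort stations upstream")
  100 * n_events / effort_days
}

#' Dichotomize a disturbance covariate at a threshold
#'
#' High/low coding for logging fraction (threshold 0.10) and road density
#' (threshold 1 km/km^2): 1 if the value is at or above the threshold.
#'
#' @param value numeric vector of finite values.
#' @param threshold cut point; values `>= threshold` code as 1.
#' @return integer vector of 0/1.
#' @export
discretize_disturbance <- function(value, threshold) {
  if (any(!is.finite(value))) stop("disturbance values must be finite")
  as.integer(value >= threshold)
}

#' Standardize to mean 0, sample SD 1
#'
#' @param values numeric vector, length >= 2, not all equal.
#' @return standardized vector.
#' @export
standardize <- function(values) {
  if (length(values) < 2) stop("need at least 2 values to standardize")
  s <- sd(values)
  if (!is.finite(s) || s == 0)
    stop("covariate is constant; drop it rather than standardizing")
  (values - mean(values)) / s
}

#' Screen covariate pairs for collinearity
#'
#' Pearson correlation and two-sided p-value for every pair of columns;
#' pairs with `|r| >= threshold` and `p < 0.05` are flagged for manual
#' exclusion before modelling.
#'
#' @param covariates data.frame or matrix of numeric covariates.
#' @param threshold absolute correlation above which a pair is flagged
#'   (default 0.6).
#' @return data.frame with `var1`, `var2`, `r`, `p`, `flagged`.
#' @export
correlation_screen <- function(covariates, threshold = 0.6) {
  m <- as.data.frame(covariates)
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("need at least 3 complete rows")
  nm <- names(m)
  pairs <- utils::combn(length(nm), 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ct <- cor.test(m[[i]], m[[j]], method = "pearson")
    data.frame(var1 = nm[i], var2 = nm[j], r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$flagged <- abs(out$r) >= threshold & out$p < 0.05
  out
}

#' Apply the multi-array species inclusion rule
#'
#' A species enters the analysis only with at least `min_total` independent
#' detections overall and detections (>= 1) in at least `min_arrays` arrays.
#'
#' @param detection_totals data.frame with columns `species`, `array_id`,
#'   `n_detections`.
#' @param min_total minimum summed detections (default 500).
#' @param min_arrays minimum number of arrays with at least one detection
#'   (default 5).
#' @return character vector of species meeting both criteria.
#' @export
species_inclusion <- function(detection_totals, min_total = 500,
                              min_arrays = 5) {
  stopifnot(all(c("species", "array_id", "n_detections") %in%
                  names(detection_totals)))
  if (any(detection_totals$n_detections < 0))
    stop("detection totals must be nonnegative")
  tot <- tapply(detection_totals$n_detections, detection_totals$species, sum)
  arr <- tapply(detection_totals$n_detections > 0,
                detection_totals$species, sum)
  sort(names(tot)[tot >= min_total & arr >= min_arrays])
}

#' Restrict events to a seasonal window
#'
#' Keeps events whose station-local civil date falls in the given months.
#' If a station table with longitudes is supplied, local time is
#' approximated as UTC plus `longitude / 15` hours; otherwise timestamps
#' are taken as already station-local.
#'
#' @param events data.frame from [filter_independent()].
#' @param months integer months to keep (default April-September, `4:9`).
#' @param stations optional station table with `station_id`, `longitude`.
#' @return the subset of `events` within the window.
#' @export
seasonal_subset <- function(events, months = 4:9, stations = NULL) {
  if (nrow(events) == 0) return(events)
  tt <- parse_timestamps(events$start_time)
  offset_h <- rep(0, nrow(events))
  if (!is.null(stations)) {
    lon <- stations$longitude[match(events$station_id, stations$station_id)]
    offset_h <- ifelse(is.na(lon), 0, lon / 15)
  }
  local_month <- as.integer(format(tt + offset_h * 3600, "%m", tz = "UTC"))
  events[local_month %in% months, , drop = FALSE]
}

#' Build the per-station covariate table
#'
#' Computes pooled recreation detection rates, standardizes the continuous
#' covariates, dichotomizes logging and road density, forms the
#' recreation x disturbance interactions and the array-level landscape
#' recreation covariate (standardized array mean of local rates).
#'
#' @param events independent detection events (already restricted to the
#'   season of interest).
#' @param stations station table; see [generate_stations()] for columns.
#' @param recreation_groups group codes pooled into the human/recreation
#'   class (default `"recreation"`; pass the full set of codes, e.g.
#'   `c("hiker", "biker", "motorized", "equestrian", "dog")`, when the raw
#'   data distinguish them).
#' @param logging_threshold,road_threshold high/low cut points
#'   (defaults 0.10 and 1 km/km^2).
#' @return data.frame with one row per station: raw and standardized
#'   recreation rate, binary disturbance codes, standardized NDVI and
#'   camera days, interactions and `landscape_recreation_std` (the array
#'   value repeated per station).
#' @export
build_covariates <- function(events, stations,
                             recreation_groups = "recreation",
                             logging_threshold = 0.1, road_threshold = 1) {
  stopifnot(is.data.frame(stations), nrow(stations) >= 2)
  if (any(stations$effort_days_season <= 0))
    stop("stations with zero seasonal effort must be excluded: ",
         paste(stations$station_id[stations$effort_days_season <= 0],
               collapse = ", "))
  rec_ev <- events[events$group %in% recreation_groups, , drop = FALSE]
  n_rec <- as.integer(table(factor(rec_ev$station_id,
                                   levels = stations$station_id)))
  rec_rate <- detection_rate(n_rec, stations$effort_days_season)
  rec_std <- standardize(rec_rate)
  logging_high <- discretize_disturbance(stations$logging_fraction,
                                         logging_threshold)
  road_high <- discretize_disturbance(stations$road_density, road_threshold)
  arr_means <- tapply(rec_rate, stations$array_id, mean)
  land_std <- standardize(as.numeric(arr_means))
  arr_levels <- as.integer(factor(stations$array_id,
                                  levels = names(arr_means)))
  data.frame(
    station_id = stations$station_id,
    array_id = stations$array_id,
    array_index = arr_levels,
    recreation_rate = rec_rate,
    recreation_rate_std = rec_std,
    logging_high = logging_high,
    road_high = road_high,
    camera_days_std = standardize(stations$effort_days_season),
    ndvi_std = standardize(stations$ndvi),
    rec_x_logging = rec_std * logging_high,
    rec_x_road = rec_std * road_high,
    landscape_recreation_std = land_std[arr_levels],
    stringsAsFactors = FALSE
  )
}

#' Assemble model-ready data for the spatial site-use model
#'
#' Counts the focal species' events per station and pairs them with the
#' covariate design from [build_covariates()].
#'
#' @param events independent, seasonally subset detection events.
#' @param stations station table.
#' @param species group code of the focal species.
#' @param ... passed to [build_covariates()].
#' @return object of class `spatial_model_data`: list with `y`, `X` (seven
#'   named columns), `array_index`, `landscape_recreation` (one value per
#'   array), `station_id`.
#' @export
build_spatial_data <- function(events, stations, species, ...) {
  cov <- build_covariates(events, stations, ...)
  sp_ev <- events[events$group == species, , drop = FALSE]
  y <- as.integer(table(factor(sp_ev$station_id,
                               levels = stations$station_id)))
  X <- as.matrix(cov[, c("recreation_rate_std", "logging_high", "road_high",
                         "camera_days_std", "ndvi_std", "rec_x_logging",
                         "rec_x_road")])
  colnames(X) <- c("recreation", "logging", "road", "camera_days", "ndvi",
                   "rec_x_logging", "rec_x_road")
  J <- max(cov$array_index)
  land <- vapply(seq_len(J), function(j)
    cov$landscape_recreation_std[match(j, cov$array_index)], numeric(1))
  structure(list(y = y, X = X, array_index = cov$array_index,
                 landscape_recreation = land,
                 station_id = stations$station_id),
            class = "spatial_model_data")
}
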