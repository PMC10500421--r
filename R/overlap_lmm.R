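# Bayesian Gaussian linear mixed model on station-level overlap
# coefficients, with a camera-array random intercept. Like the count model
# it carries no fixed intercept: the array intercepts (mean zero) absorb
# the grand mean of the response, so covariates should be centred or
# binary and the response is analysed on its natural [0, 1] scale.

validate_overlap_data <- function(data) {
  stopifnot(is.list(data), !is.null(data$y), !is.null(data$X),
            !is.null(data$array_index))
  y <- as.numeric(data$y); X <- as.matrix(data$X)
  ai <- as.integer(data$array_index)
  if (length(y) != nrow(X) || length(ai) != length(y))
    stop("y, X and array_index must align")
  if (anyNA(y) || anyNA(X) || anyNA(ai))
    stop("model data must not contain missing values")
  if (any(y < 0 | y > 1))
    stop("overlap response must lie in [0, 1]")
  if (length(y) < 10) stop("need at least 10 stations")
  J <- max(ai)
  if (length(unique(ai)) < 2)
    stop("need at least 2 arrays (random intercept unidentifiable)")
  if (!setequal(unique(ai), seq_len(J)))
    stop("array_index must cover 1..J")
  if (qr(X)$rank < ncol(X) || kappa(X) > 1e8)
    stop("design matrix is (near-)collinear")
  list(y = y, X = X, array_index = ai, J = J)
}

#' Fit the Gaussian mixed model for overlap coefficients
#'
#' Posterior sampling for
#' \deqn{overlap_i \sim N(\sum_k \beta_k x_{ik} + \epsilon_{array(i)},
#'       \sigma^2), \quad \epsilon_j \sim N(0, \sigma_{array}^2)}
#' with priors `beta ~ U(-10, 10)` and both SDs `~ U(0, 10)`. Convergence
#' is assessed with split-chain R-hat as in [fit_spatial()].
#'
#' @param data list with `y` (overlap coefficients in `[0, 1]`), `X`
#'   (named design columns, e.g. logging/road indicators and standardized
#'   detection counts) and `array_index`.
#' @param config an [mcmc_config()]; the survey-scale profile for this
#'   model uses a thinning rate of 3.
#' @return a `posterior_draws` object with parameters `beta_<column>`,
#'   `sigma_array`, `sigma_resid` and `eps_<j>`.
#' @export
fit_overlap_lmm <- function(data, config = mcmc_profile("test", thin = 3)) {
  d <- validate_overlap_data(data)
  p <- ncol(d$X)
  cn <- colnames(d$X)
  if (is.null(cn)) cn <- paste0("x", seq_len(p))
  par_names <- c(paste0("beta_", cn), paste0("eps_", seq_len(d$J)),
                 "sigma_array", "sigma_resid")
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + ch)
    init <- c(rnorm(p, 0, 0.2), rnorm(d$J, 0, 0.2),
              runif(1, 0.05, 0.5), runif(1, 0.05, 0.5))
    res <- mwg_lmm_sampler(d$y, d$X, d$array_index, config$iterations,
                           config$burn_in, config$thin, init, 10, 10)
    colnames(res$draws) <- par_names
    chains[[ch]] <- res$draws
  }
  rhat <- vapply(par_names, function(pn)
    gelman_rubin(sapply(chains, function(m) m[, pn])), numeric(1))
  converged <- all(rhat <= 1.1)
  if (!converged)
    warning("MCMC not converged: max R-hat = ",
            format(max(rhat), digits = 4), call. = FALSE)
  new_posterior_draws(chains, "overlap_lmm", config, rhat, converged)
}

#' Assemble the design for an overlap mixed model
#'
#' Joins per-station overlap coefficients with station covariates for one
#' of the two standard model forms: the focal-vs-recreation model
#' (logging, road, standardized carnivore detection rate, standardized
#' detection counts of both groups) or the focal-vs-carnivore model
#' (standardized recreation rate, logging, road, standardized detection
#' counts of both groups).
#'
#' @param overlaps data.frame from [station_overlaps()].
#' @param covariates data.frame from [build_covariates()].
#' @param extra_rates named list of additional per-station detection-rate
#'   vectors (aligned with `covariates$station_id`) to standardize and
#'   include, e.g. `list(carnivore_rate = ...)`.
#' @param use_recreation include the standardized local recreation rate as
#'   a covariate (the focal-vs-carnivore form).
#' @return list with `y`, `X`, `array_index`, `station_id` ready for
#'   [fit_overlap_lmm()].
#' @export
build_overlap_data <- function(overlaps, covariates, extra_rates = list(),
                               use_recreation = FALSE) {
  idx <- match(overlaps$station_id, covariates$station_id)
  if (anyNA(idx)) stop("overlap stations missing from covariate table")
  cov <- covariates[idx, , drop = FALSE]
  cols <- list(logging = cov$logging_high, road = cov$road_high)
  if (use_recreation)
    cols <- c(list(recreation = standardize(cov$recreation_rate)), cols)
  for (nm in names(extra_rates)) {
    v <- extra_rates[[nm]][idx]
    cols[[nm]] <- standardize(v)
  }
  cols$n_1 <- standardize(overlaps$n1)
  cols$n_2 <- standardize(overlaps$n2)
  X <- do.call(cbind, cols)
  ai <- as.integer(factor(cov$array_index))
  list(y = overlaps$delta4, X = X, array_index = ai,
       station_id = overlaps$station_id)
}
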