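# Posterior containers, convergence diagnostics and credible-interval
# evidence classification shared by both Bayesian models.

new_posterior_draws <- function(chains, model, config, rhat = NULL,
                                converged = NA) {
  stopifnot(is.list(chains), length(chains) >= 1)
  structure(list(chains = chains, parameters = colnames(chains[[1]]),
                 model = model, config = config, rhat = rhat,
                 converged = converged),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws (", x$model, "): ", length(x$chains), " chains x ",
      nrow(x$chains[[1]]), " draws, ", length(x$parameters),
      " parameters\n", sep = "")
  if (!is.null(x$rhat))
    cat("max R-hat:", format(max(x$rhat), digits = 4),
        if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Pool posterior draws across chains
#'
#' @param x a `posterior_draws` object.
#' @param ... unused.
#' @return matrix with one column per parameter, chains stacked.
#' @export
as.matrix.posterior_draws <- function(x, ...) {
  do.call(rbind, x$chains)
}

#' Long-format posterior draws
#'
#' @param x a `posterior_draws` object.
#' @param ... unused.
#' @return data.frame with `chain`, `iteration`, `parameter`, `value`.
#' @export
as.data.frame.posterior_draws <- function(x, ...) {
  n <- nrow(x$chains[[1]]); p <- length(x$parameters)
  do.call(rbind, lapply(seq_along(x$chains), function(ch) {
    data.frame(chain = ch, iteration = rep(seq_len(n), p),
               parameter = rep(x$parameters, each = n),
               value = as.vector(x$chains[[ch]]),
               stringsAsFactors = FALSE)
  }))
}

#' Gelman-Rubin potential scale reduction factor (split chains)
#'
#' Computes the split-chain R-hat for one parameter: each chain is halved,
#' and the factor is `sqrt(((n - 1)/n * W + B/n) / W)` with `W` the mean
#' within-chain variance and `B/n` the variance of chain means.
#'
#' @param draws matrix (iterations x chains), or list of equal-length
#'   numeric vectors, one per chain.
#' @return the R-hat value.
#' @export
gelman_rubin <- function(draws) {
  if (is.list(draws) && !is.data.frame(draws)) {
    lens <- lengths(draws)
    if (length(unique(lens)) != 1) stop("chains must have equal lengths")
    draws <- do.call(cbind, draws)
  }
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("need at least 2 chains")
  if (nrow(draws) < 10) stop("need at least 10 draws per chain")
  half <- floor(nrow(draws) / 2)
  split <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j)
    cbind(draws[seq_len(half), j], draws[half + seq_len(half), j])))
  n <- nrow(split)
  w <- mean(apply(split, 2, var))
  if (!is.finite(w) || w == 0)
    stop("zero within-chain variance; R-hat undefined")
  b_over_n <- var(colMeans(split))
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

#' Equal-tailed credible interval
#'
#' @param samples numeric vector of posterior draws (>= 100).
#' @param level interval mass, e.g. 0.95 or 0.80.
#' @return numeric `c(lo, hi)` from linear-interpolation (type 7) quantiles.
#' @export
credible_interval <- function(samples, level = 0.95) {
  if (length(samples) < 100) stop("need at least 100 samples")
  a <- (1 - level) / 2
  unname(quantile(samples, c(a, 1 - a), type = 7))
}

#' Classify evidence from nested credible intervals
#'
#' Strong evidence if the 95% interval excludes zero; weak if only the 80%
#' interval does; none otherwise. The sign is taken from the excluding
#' interval.
#'
#' @param ci95,ci80 numeric `c(lo, hi)`; `ci80` must nest inside `ci95`.
#' @return list with `class` (`"strong"`, `"weak"`, `"none"`) and `sign`
#'   (`"+"`, `"-"`, `"0"`).
#' @export
classify_evidence <- function(ci95, ci80) {
  tol <- 1e-12
  if (ci80[1] < ci95[1] - tol || ci80[2] > ci95[2] + tol)
    stop("80% interval must be nested within the 95% interval")
  excl <- function(ci) ci[1] > 0 || ci[2] < 0
  if (excl(ci95)) {
    list(class = "strong", sign = if (ci95[1] > 0) "+" else "-")
  } else if (excl(ci80)) {
    list(class = "weak", sign = if (ci80[1] > 0) "+" else "-")
  } else {
    list(class = "none", sign = "0")
  }
}

#' Summarize a posterior into an evidence table
#'
#' Per parameter: posterior mean, 95% and 80% equal-tailed intervals,
#' evidence class and sign, and (when available) the R-hat recorded at
#' fitting time.
#'
#' @param draws a `posterior_draws` object.
#' @param parameters subset of parameter names (default: all).
#' @return data.frame of class `evidence_summary`.
#' @export
summarize_posterior <- function(draws, parameters = NULL) {
  stopifnot(inherits(draws, "posterior_draws"))
  pooled <- as.matrix(draws)
  if (is.null(parameters)) parameters <- draws$parameters
  rows <- lapply(parameters, function(p) {
    s <- pooled[, p]
    ci95 <- credible_interval(s, 0.95)
    ci80 <- credible_interval(s, 0.80)
    ev <- classify_evidence(ci95, ci80)
    data.frame(parameter = p, mean = mean(s),
               ci95_lo = ci95[1], ci95_hi = ci95[2],
               ci80_lo = ci80[1], ci80_hi = ci80[2],
               class = ev$class, sign = ev$sign,
               rhat = if (!is.null(draws$rhat)) unname(draws$rhat[p]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("evidence_summary", "data.frame")
  out
}

#' @export
print.evidence_summary <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-28s = %6.2f, 95%% CI: %.2f to %.2f [%s%s]\n",
                x$parameter[i], x$mean[i], x$ci95_lo[i], x$ci95_hi[i],
                x$class[i],
                if (x$sign[i] != "0") paste0(", ", x$sign[i]) else ""))
  }
  invisible(x)
}
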