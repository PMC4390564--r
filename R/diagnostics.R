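#' Shortest (highest posterior density) interval
#'
#' The shortest interval containing a fraction `prob` of the draws: sort
#' the chain and take the narrowest window covering `ceiling(prob * n)`
#' draws. By construction its width never exceeds that of the equal-tail
#' interval at the same level.
#'
#' @param x numeric vector of posterior draws.
#' @param prob coverage probability (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2) stop("need at least two finite draws")
  k <- min(max(ceiling(prob * n), 2L), n)
  lo <- x[seq_len(n - k + 1L)]
  hi <- x[k:n]
  i <- which.min(hi - lo)
  c(lower = lo[i], upper = hi[i])
}

#' Posterior summary table
#'
#' Posterior mean (PM), posterior standard deviation (PSD) and the 95%
#' highest posterior density interval (HPD95) for every stored chain,
#' including the derived chains (v, 1 - v, h2, gamma2) that are computed
#' per stored cycle as ratios of the variance draws.
#'
#' @param samples an [run_gibbs()] result, or a matrix of draws with
#'   column names.
#' @param prob HPD coverage (default 0.95).
#' @return A data frame with columns `parameter`, `mean`, `sd`, `hpd_lower`,
#'   `hpd_upper`.
#' @export
posterior_summary <- function(samples, prob = 0.95) {
  draws <- if (inherits(samples, "epi_samples")) samples$draws else
    as.matrix(samples)
  if (nrow(draws) < 50)
    warning("fewer than 50 stored draws: HPD bounds are unstable")
  rows <- lapply(colnames(draws), function(nm) {
    x <- draws[, nm]
    if (sd(x) == 0)
      warning("chain '", nm, "' is constant; degenerate HPD interval")
    h <- if (sd(x) > 0) hpd_interval(x, prob) else c(x[1], x[1])
    data.frame(parameter = nm, mean = mean(x), sd = sd(x),
               hpd_lower = h[[1]], hpd_upper = h[[2]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Spectral density of a chain at frequency zero, via an AR fit
# (the variance inflation used by the Geweke z-score and ESS).
spectrum0 <- function(x) {
  x <- as.numeric(x)
  if (length(unique(x)) == 1L) return(0)
  fit <- try(stats::ar(x, aic = TRUE,
                       order.max = min(30L, floor(length(x) / 4))),
             silent = TRUE)
  if (inherits(fit, "try-error") || !length(fit$ar))
    return(stats::var(x))
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first `frac1` of a chain with the mean of the
#' last `frac2`, standardised by spectral-density estimates of the
#' respective Monte Carlo variances. |z| values beyond about 3 indicate
#' the early part of the chain has not reached the stationary
#' distribution.
#'
#' @param x numeric chain.
#' @param frac1,frac2 fractions of the chain compared (defaults 0.1, 0.5).
#' @return The z statistic.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(floor(frac1 * n), 2L))]
  b <- x[seq.int(n - max(floor(frac2 * n), 2L) + 1L, n)]
  v <- spectrum0(a) / length(a) + spectrum0(b) / length(b)
  if (v <= 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(v)
}

#' Effective sample size
#'
#' `n * var(x) / spectrum0(x)`: the number of independent draws carrying
#' the same information as the autocorrelated chain.
#'
#' @param x numeric chain.
#' @return Effective sample size (capped at `length(x)` is *not* applied;
#'   slightly larger values can occur for antithetic chains).
#' @export
effective_size <- function(x) {
  s0 <- spectrum0(x)
  if (s0 <= 0) return(0)
  length(x) * stats::var(x) / s0
}

#' Convergence diagnostics for all chains
#'
#' Geweke z-scores (first 10% vs last 50%) and effective sample sizes per
#' parameter, with advisory pass flags. Purely advisory: no error is ever
#' raised.
#'
#' @param samples an [run_gibbs()] result or a draws matrix.
#' @param z_threshold flag chains with `|z|` above this (default 3).
#' @param min_ess flag chains with ESS below this (default 100).
#' @return Data frame with `parameter`, `geweke_z`, `ess`, `ok`.
#' @export
convergence_diagnostics <- function(samples, z_threshold = 3,
                                    min_ess = 100) {
  draws <- if (inherits(samples, "epi_samples")) samples$draws else
    as.matrix(samples)
  if (nrow(draws) < 100)
    warning("fewer than 100 stored draws: diagnostics are unreliable")
  out <- do.call(rbind, lapply(colnames(draws), function(nm) {
    z <- geweke_z(draws[, nm])
    ess <- effective_size(draws[, nm])
    data.frame(parameter = nm, geweke_z = z, ess = ess,
               ok = is.finite(z) && abs(z) <= z_threshold && ess >= min_ess)
  }))
  rownames(out) <- NULL
  out
}

#' Log conditional predictive ordinate (LogCPO)
#'
#' Pseudo-log-marginal probability of the data: for each datum the
#' leave-one-out predictive density is estimated by the harmonic mean of
#' the per-draw observation densities,
#' \deqn{\hat p(y_i | y_{-i}) = N_s \Big[\sum_{j=1}^{N_s}
#'   1/p(y_i | \theta_j)\Big]^{-1},}
#' where \eqn{p(y_i | \theta_j)} is Normal with the draw's fitted location
#' for record i and residual variance \eqn{\sigma_e^2(\theta_j)}; LogCPO is
#' the sum of the logs, computed with log-sum-exp stabilisation. Larger is
#' better. Any datum with zero predictive density contributes `-Inf` and
#' is reported in the `per_datum` attribute.
#'
#' @param samples an [run_gibbs()] result obtained with
#'   `store_fitted = TRUE`, or a list with elements `fitted` (draws x
#'   records matrix) and `sigma_e2` (vector of residual-variance draws).
#' @param y observed phenotypes (defaults to those stored in `samples`).
#' @return LogCPO (scalar), with attribute `per_datum`.
#' @export
log_cpo <- function(samples, y = NULL) {
  if (inherits(samples, "epi_samples")) {
    if (is.null(samples$fitted))
      stop("run_gibbs() must be called with store_fitted = TRUE for LogCPO")
    fitted <- samples$fitted
    sige2 <- samples$draws[, "sigma_e2"]
    if (is.null(y)) y <- samples$y
  } else {
    fitted <- samples$fitted
    sige2 <- samples$sigma_e2
  }
  Ns <- nrow(fitted)
  stopifnot(length(y) == ncol(fitted), length(sige2) == Ns)
  sig <- sqrt(sige2)
  per <- vapply(seq_along(y), function(i) {
    nlp <- -dnorm(y[i], fitted[, i], sig, log = TRUE)   # -log p(y_i|theta_j)
    m <- max(nlp)
    if (!is.finite(m)) return(-Inf)
    log(Ns) - (m + log(sum(exp(nlp - m))))
  }, numeric(1))
  structure(sum(per), per_datum = per)
}
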