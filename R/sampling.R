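#' Single-site Gibbs sweep over the location effects
#'
#' Replaces each coordinate of the solution vector, in fixed ascending
#' order, by a draw from its univariate normal full conditional
#' \eqn{s_i \sim N((r_i - \sum_{j \ne i} c_{ij} s_j)/c_{ii},
#' \sigma_e^2/c_{ii})}.
#'
#' @param sys an [build_mme()] system (or any list with sparse `C`, `r`,
#'   `s`).
#' @param sigma_e2 residual variance (> 0).
#' @param s optional state vector to start the sweep from (defaults to
#'   `sys$s`).
#' @return The updated state vector after one full sweep.
#' @export
sample_location <- function(sys, sigma_e2, s = sys$s) {
  stopifnot(sigma_e2 > 0)
  C <- as(as(sys$C, "generalMatrix"), "CsparseMatrix")
  cpp_sweep_location(C@p, C@i, C@x, sys$r, as.numeric(s), sigma_e2)
}

#' Draw the autorecursive parameter lambda
#'
#' Full conditional of lambda given the epigenetic effects `w`. In mode
#' `"paper_tn"` the draw is from a truncated normal on (0, 0.5) with
#' \deqn{\mu_\lambda = \frac{\sum_{both} (w_f + w_m) w_i / (1 - 2\lambda^2)
#'   + \sum_{one} w_p w_i / (1 - \lambda^2)}
#'  {\sum_{both} (w_f + w_m)^2 / (1 - 2\lambda^2)
#'   + \sum_{one} w_p^2 / (1 - \lambda^2)}}
#' and variance \eqn{\sigma_w^2} over the same denominator, all
#' \eqn{(1 - \cdot\lambda^2)} factors evaluated at the current lambda. This
#' conditional treats those factors as constants, so it is an approximate
#' Gibbs step; mode `"metropolis_exact"` uses the same truncated normal as
#' a proposal and accepts or rejects against the exact conditional
#' \eqn{\prod_i N(w_i;\ \lambda(w_f + w_m),\ d_i(\lambda)\sigma_w^2)},
#' which keeps the lambda-dependence of the residual epigenetic variances
#' \eqn{d_i}.
#'
#' When the parental sums of squares vanish (e.g. all parental `w` are
#' zero, or a founders-only pedigree) the data carry no information and a
#' uniform(0, 0.5) prior draw is returned.
#'
#' @param w numeric vector of epigenetic effects in pedigree order.
#' @param ped an [pedigree()] object.
#' @param sigma_w2 epigenetic variance (> 0).
#' @param current_lambda current value of lambda.
#' @param mode `"paper_tn"` or `"metropolis_exact"`.
#' @return A single draw of lambda in (0, 0.5). For `"metropolis_exact"`
#'   the attribute `"accepted"` reports whether the proposal was taken.
#' @export
sample_lambda <- function(w, ped, sigma_w2, current_lambda,
                          mode = c("paper_tn", "metropolis_exact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ped, "epi_pedigree"), length(w) == ped$n,
            sigma_w2 > 0)
  check_lambda(current_lambda)
  if (all(ped$sire == 0L & ped$dam == 0L)) {
    warning("no non-founders: lambda is unidentifiable, drawing from prior")
    return(runif(1, 0, 0.5))
  }
  st <- cpp_lambda_stats(ped$sire, ped$dam, w)
  tn_par <- function(lam) {
    db <- 1 - 2 * lam^2
    dn <- 1 - lam^2
    den <- st[["sq_both"]] / db + st[["sq_one"]] / dn
    num <- st[["cross_both"]] / db + st[["cross_one"]] / dn
    c(mu = num / den, sd = sqrt(sigma_w2 / den), den = den)
  }
  p0 <- tn_par(current_lambda)
  if (mode == "paper_tn") {
    if (!(p0[["den"]] > 0)) return(runif(1, 0, 0.5))
    return(cpp_tn_draw(1L, p0[["mu"]], p0[["sd"]]))
  }
  # Metropolis-Hastings against the exact conditional
  ld <- function(lam)
    cpp_lambda_logdens(lam, ped$sire, ped$dam, w, sigma_w2)
  if (!(p0[["den"]] > 0)) {
    prop <- runif(1, 0, 0.5)
    log_acc <- ld(prop) - ld(current_lambda)
  } else {
    prop <- cpp_tn_draw(1L, p0[["mu"]], p0[["sd"]])
    pp <- tn_par(prop)
    log_acc <- ld(prop) - ld(current_lambda) +
      tn_logdens05(current_lambda, pp[["mu"]], pp[["sd"]]) -
      tn_logdens05(prop, p0[["mu"]], p0[["sd"]])
  }
  accepted <- log(runif(1)) < log_acc
  structure(if (accepted) prop else current_lambda, accepted = accepted)
}

# log density of a normal(mu, sd) truncated to [0, 0.5]
tn_logdens05 <- function(x, mu, sd) {
  z <- pnorm((0.5 - mu) / sd) - pnorm((0 - mu) / sd)
  dnorm(x, mu, sd, log = TRUE) - log(max(z, 1e-300))
}

#' Draw a variance component from its scaled inverse chi-square conditional
#'
#' Returns `(quadratic + prior_s2) / rchisq(count + prior_n)`: the
#' conjugate update for a normal variance, where `quadratic` is the
#' structure-weighted sum of squares of the effects (`u'A^-1 u`,
#' `w'T^-1 w`, `e'e`, ...) and `count` the number of effects (or records).
#' With `prior_s2 = 0, prior_n = -2` this is the flat prior on the
#' variance.
#'
#' @param quadratic sum of squares (>= 0).
#' @param count number of effect levels or data.
#' @param prior_s2,prior_n prior scale and degrees of belief.
#' @param label term name used in error messages.
#' @return One draw of the variance.
#' @export
sample_variance <- function(quadratic, count, prior_s2 = 0, prior_n = -2,
                            label = "variance") {
  if (quadratic < 0) stop("quadratic form must be nonnegative")
  df <- count + prior_n
  if (df <= 0)
    stop("posterior degrees of freedom for ", label,
         " are not positive (count ", count, " + prior n ", prior_n, ")")
  (quadratic + prior_s2) / rchisq(1, df)
}

#' Draw the 2x2 direct/maternal genetic covariance matrix G
#'
#' Inverse-Wishart full conditional by conjugacy: scale
#' `[u'A^-1 u, u'A^-1 m; ., m'A^-1 m] + G0` and degrees of freedom
#' `n + n_G`, where `n` is the pedigree size. The mean of the draws is
#' approximately `scale / (df - 3)` for this 2x2 case.
#'
#' @param u,m direct and maternal genetic effect vectors (pedigree order).
#' @param A_inv sparse inverse numerator relationship matrix.
#' @param n_G,G0 prior hyperparameters (`n_G = -3`, `G0 = 0` is flat).
#' @return A symmetric positive definite 2x2 matrix.
#' @export
sample_G <- function(u, m, A_inv, n_G = -3, G0 = matrix(0, 2, 2)) {
  n <- length(u)
  stopifnot(length(m) == n, all(dim(A_inv) == n))
  df <- n + n_G
  if (df <= 1) stop("posterior degrees of freedom for G must exceed 1")
  Au <- as.numeric(A_inv %*% u)
  Am <- as.numeric(A_inv %*% m)
  S <- matrix(c(sum(u * Au), sum(u * Am), sum(u * Am), sum(m * Am)),
              2, 2) + G0
  if (det(S) <= 0 || S[1, 1] <= 0)
    stop("inverse-Wishart scale matrix is not positive definite")
  W <- stats::rWishart(1, df, solve(S))[, , 1]
  G <- solve(W)
  (G + t(G)) / 2
}
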