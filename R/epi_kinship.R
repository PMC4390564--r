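#' Map the reset coefficient to the autorecursive parameter
#'
#' The reset coefficient \eqn{v \in [0, 1]} is the expected proportion of
#' parental epigenetic marks erased at meiosis; its complement \eqn{1 - v}
#' is the epigenetic transmission coefficient, split equally between the two
#' parents: \eqn{\lambda = (1 - v)/2}.
#'
#' @param v reset coefficient(s) in `[0, 1]`.
#' @return \eqn{\lambda = (1 - v)/2}, in `[0, 0.5]`.
#' @examples
#' lambda_from_reset(0.40)  # 0.30
#' lambda_from_reset(0.80)  # 0.10
#' @export
lambda_from_reset <- function(v) {
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("reset coefficient v must lie in [0, 1]")
  (1 - v) / 2
}

#' @rdname lambda_from_reset
#' @param lambda autorecursive parameter(s) in `[0, 0.5]`.
#' @export
reset_from_lambda <- function(lambda) {
  check_lambda(lambda)
  1 - 2 * lambda
}

check_lambda <- function(lambda) {
  if (length(lambda) < 1 || any(!is.finite(lambda)) ||
      any(lambda < 0) || any(lambda > 0.5))
    stop("lambda must lie in [0, 0.5]")
  invisible(lambda)
}

#' Epigenetic relationship matrix T (dense)
#'
#' Covariance structure (relative to \eqn{\sigma_w^2}) of transgenerational
#' epigenetic effects under the recursion
#' \eqn{w_i = \lambda w_{f_i} + \lambda w_{m_i} + \varepsilon_i}, with
#' \eqn{V(\varepsilon_i)/\sigma_w^2 = 1} for founders, \eqn{1 - \lambda^2}
#' with one known parent and \eqn{1 - 2\lambda^2} with both known, so that
#' the epigenetic variance is stationary across generations. Computed by the
#' tabular recursion `t_ij = lambda * (t(j, sire) + t(j, dam))` with
#' diagonal \eqn{t_{ii} = \lambda^2 (t_{ff} + 2 t_{fm} + t_{mm}) + d_i},
#' i.e. exactly \eqn{T = (I-P)^{-1} V(\varepsilon) (I-P)^{-T} / \sigma_w^2}.
#' The diagonal equals 1 whenever mates are epigenetically unrelated (as the
#' model assumes). At `lambda = 0` T is the identity; at `lambda = 0.5` it
#' equals the numerator relationship matrix A on non-inbred pedigrees.
#'
#' Dense construction is intended for reference and testing; at scale only
#' the sparse inverse [build_T_inverse()] is needed, and setting up T itself
#' is the costlier of the two.
#'
#' @param ped an [pedigree()] object.
#' @param lambda autorecursive parameter in `[0, 0.5]`.
#' @param max_n refuse pedigrees with more individuals than this.
#' @return Dense symmetric `n x n` matrix T.
#' @export
build_T <- function(ped, lambda, max_n = 2000) {
  stopifnot(inherits(ped, "epi_pedigree"))
  check_lambda(lambda)
  n <- ped$n
  if (n > max_n)
    stop("pedigree has ", n, " individuals; dense T is capped at max_n = ",
         max_n)
  s <- ped$sire
  d <- ped$dam
  TT <- diag(n)
  for (i in seq_len(n)) {
    np <- (s[i] > 0L) + (d[i] > 0L)
    di <- c(1, 1 - lambda^2, 1 - 2 * lambda^2)[np + 1L]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s[i] > 0L) row <- row + TT[j, s[i]]
      if (d[i] > 0L) row <- row + TT[j, d[i]]
      TT[i, j] <- TT[j, i] <- lambda * row
    }
    quad <- 0
    if (s[i] > 0L) quad <- quad + TT[s[i], s[i]]
    if (d[i] > 0L) quad <- quad + TT[d[i], d[i]]
    if (s[i] > 0L && d[i] > 0L) quad <- quad + 2 * TT[s[i], d[i]]
    TT[i, i] <- lambda^2 * quad + di
  }
  TT
}

#' Sparse inverse of the epigenetic relationship matrix
#'
#' One pedigree pass, mirroring Henderson's rules for the inverse numerator
#' relationship matrix. With both parents known and
#' \eqn{d = 1/(1 - 2\lambda^2)}: add \eqn{d} at (i,i), \eqn{-\lambda d} at
#' (i,sire) and (i,dam), and \eqn{\lambda^2 d} at (sire,sire), (dam,dam) and
#' (sire,dam). With one known parent p and \eqn{d = 1/(1 - \lambda^2)}: add
#' \eqn{d} at (i,i), \eqn{-\lambda d} at (i,p) and \eqn{\lambda^2 d} at
#' (p,p). Founders add 1 at (i,i). The same rule applies whether the known
#' parent is the sire or the dam. The sparsity pattern depends only on the
#' pedigree; only the values depend on `lambda`, which is what makes the
#' per-iteration rebuild inside the Gibbs sampler cheap.
#'
#' @inheritParams build_T
#' @return A symmetric sparse [Matrix::Matrix] (class `dsCMatrix`).
#' @export
build_T_inverse <- function(ped, lambda) {
  stopifnot(inherits(ped, "epi_pedigree"))
  check_lambda(lambda)
  relationship_inverse(ped, rule = "T", lambda = lambda)
}

#' Expected phenotypic covariance between relatives
#'
#' Closed-form covariance contributed by additive genetic and
#' transgenerational epigenetic effects for the four classic relative
#' classes: parent--offspring \eqn{\sigma_u^2/2 + \lambda\sigma_w^2},
#' full sibs \eqn{\sigma_u^2/2 + 2\lambda^2\sigma_w^2}, half sibs
#' \eqn{\sigma_u^2/4 + \lambda^2\sigma_w^2}, and uncle--nephew
#' \eqn{\sigma_u^2/4 + 2\lambda^3\sigma_w^2}. Although parent--offspring and
#' full sibs share the additive relationship 1/2 (and half sibs and
#' uncle--nephew share 1/4), each extra meiosis separating the pair gives
#' the epigenetic marks one more opportunity to reset, so the epigenetic
#' contribution is ordered strictly within each pair of classes for
#' \eqn{0 < \lambda < 0.5}.
#'
#' @param relationship one of `"parent_offspring"`, `"full_sibs"`,
#'   `"half_sibs"`, `"uncle_nephew"`.
#' @param sigma_u2 additive genetic variance (>= 0).
#' @param sigma_w2 transgenerational epigenetic variance (>= 0).
#' @param lambda autorecursive parameter in `[0, 0.5]`.
#' @return Expected covariance in trait variance units.
#' @examples
#' expected_relative_covariance("parent_offspring", 90, 60, 0.10)  # 51
#' @export
expected_relative_covariance <- function(relationship = c("parent_offspring",
                                                          "full_sibs",
                                                          "half_sibs",
                                                          "uncle_nephew"),
                                         sigma_u2, sigma_w2, lambda) {
  relationship <- match.arg(relationship)
  if (sigma_u2 < 0 || sigma_w2 < 0) stop("variances must be nonnegative")
  check_lambda(lambda)
  switch(relationship,
    parent_offspring = 0.5 * sigma_u2 + lambda * sigma_w2,
    full_sibs        = 0.5 * sigma_u2 + 2 * lambda^2 * sigma_w2,
    half_sibs        = 0.25 * sigma_u2 + lambda^2 * sigma_w2,
    uncle_nephew     = 0.25 * sigma_u2 + 2 * lambda^3 * sigma_w2)
}

#' Heritability and epigenetic heritability
#'
#' \eqn{h^2 = \sigma_u^2 / (\sigma_u^2 + \sigma_w^2 + \sigma_e^2)} and
#' \eqn{\gamma^2 = \sigma_w^2 / (\sigma_u^2 + \sigma_w^2 + \sigma_e^2)}.
#'
#' @param sigma_u2,sigma_w2,sigma_e2 variance components (>= 0, not all 0).
#' @return Named numeric vector `c(h2 = ..., gamma2 = ...)`.
#' @examples
#' variance_ratios(210, 120, 270)  # h2 = 0.35, gamma2 = 0.20
#' @export
variance_ratios <- function(sigma_u2, sigma_w2, sigma_e2) {
  if (any(c(sigma_u2, sigma_w2, sigma_e2) < 0))
    stop("variances must be nonnegative")
  tot <- sigma_u2 + sigma_w2 + sigma_e2
  if (tot <= 0) stop("at least one variance component must be positive")
  c(h2 = sigma_u2 / tot, gamma2 = sigma_w2 / tot)
}

#' Dump a sparse symmetric matrix as coordinate triplets
#'
#' Debug/interchange format: one `row col value` line per stored entry of
#' the lower triangle, 1-based indices, whitespace-delimited.
#'
#' @param M a (sparse) matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_triplets <- function(M, path) {
  Tm <- as(as(M, "generalMatrix"), "TsparseMatrix")
  keep <- Tm@i >= Tm@j
  writeLines(paste(Tm@i[keep] + 1L, Tm@j[keep] + 1L,
                   format(Tm@x[keep], digits = 17)), path)
  invisible(path)
}
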