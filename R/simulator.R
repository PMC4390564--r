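#' Configuration for the population simulator
#'
#' Describes a discrete-generation population: a base generation of
#' unrelated founders (half sires, half dams) followed by `n_generations`
#' of full-sib families whose sire and dam are sampled at random from the
#' previous generation. The defaults are the simulation conditions used
#' throughout: 3000 founders (1500 sires, 1500 dams), two descendant
#' generations of 3000 full-sib families of 10, a general mean of 100
#' units, and the "high epigenetic signal" parameter set
#' \eqn{\sigma_u^2 = 210, \sigma_w^2 = 120, \sigma_e^2 = 270,
#' \lambda = 0.30} (h2 = 0.35, gamma2 = 0.20, v = 0.40); the companion
#' preset `dataset2` is \eqn{\sigma_u^2 = 90, \sigma_w^2 = 60,
#' \sigma_e^2 = 450, \lambda = 0.10} (h2 = 0.15, gamma2 = 0.10, v = 0.80).
#'
#' `epi_offspring_variance` selects the conditional variance of a
#' descendant's epigenetic effect: `"model_consistent"` (default) uses
#' \eqn{(1 - 2\lambda^2)\sigma_w^2}, which keeps the epigenetic variance
#' stationary across generations and matches the covariance model the
#' sampler fits; `"paper_as_written"` uses \eqn{(1 - \lambda)^2\sigma_w^2},
#' a variant retained for replication studies that breaks stationarity.
#'
#' @param n_base number of founders (even; half male, half female).
#' @param n_families full-sib families per descendant generation.
#' @param family_size offspring per family.
#' @param n_generations descendant generations beyond the base.
#' @param mu general mean, trait units.
#' @param sigma_u2,sigma_w2,sigma_e2 additive, epigenetic and residual
#'   variances.
#' @param lambda autorecursive parameter in `[0, 0.5]`.
#' @param seed integer seed; the same config is bit-reproducible.
#' @param epi_offspring_variance see Details.
#' @return An object of class `epi_sim_config`.
#' @export
sim_config <- function(n_base = 3000, n_families = 3000, family_size = 10,
                       n_generations = 2, mu = 100,
                       sigma_u2 = 210, sigma_w2 = 120, sigma_e2 = 270,
                       lambda = 0.30, seed = 1,
                       epi_offspring_variance = c("model_consistent",
                                                  "paper_as_written")) {
  epi_offspring_variance <- match.arg(epi_offspring_variance)
  if (n_base < 2 || n_base %% 2 != 0)
    stop("n_base must be an even number >= 2")
  if (any(c(sigma_u2, sigma_w2, sigma_e2) < 0))
    stop("variances must be nonnegative")
  check_lambda(lambda)
  structure(
    list(n_base = as.integer(n_base), n_families = as.integer(n_families),
         family_size = as.integer(family_size),
         n_generations = as.integer(n_generations),
         mu = mu, sigma_u2 = sigma_u2, sigma_w2 = sigma_w2,
         sigma_e2 = sigma_e2, lambda = lambda, seed = as.integer(seed),
         epi_offspring_variance = epi_offspring_variance),
    class = "epi_sim_config")
}

#' Named simulation presets
#'
#' `"dataset1"`: \eqn{\sigma_u^2 = 210, \sigma_w^2 = 120,
#' \sigma_e^2 = 270, \lambda = 0.30} (v = 0.40).
#' `"dataset2"`: \eqn{\sigma_u^2 = 90, \sigma_w^2 = 60, \sigma_e^2 = 450,
#' \lambda = 0.10} (v = 0.80). Additional arguments (population sizes,
#' seed, ...) are passed to [sim_config()].
#'
#' @param name `"dataset1"` or `"dataset2"`.
#' @param ... overrides passed to [sim_config()].
#' @return An `epi_sim_config`.
#' @export
sim_preset <- function(name = c("dataset1", "dataset2"), ...) {
  name <- match.arg(name)
  pars <- switch(name,
    dataset1 = list(sigma_u2 = 210, sigma_w2 = 120, sigma_e2 = 270,
                    lambda = 0.30),
    dataset2 = list(sigma_u2 = 90, sigma_w2 = 60, sigma_e2 = 450,
                    lambda = 0.10))
  do.call(sim_config, utils::modifyList(pars, list(...)))
}

#' Simulate a population with genetic and epigenetic inheritance
#'
#' Founders receive \eqn{u \sim N(0, \sigma_u^2)} and
#' \eqn{w \sim N(0, \sigma_w^2)}. Each descendant family draws a sire from
#' the previous generation's males and a dam from its females (uniformly,
#' with replacement across families); offspring receive
#' \eqn{u_j \sim N((u_f + u_m)/2, \sigma_u^2/2)} and
#' \eqn{w_j \sim N(\lambda w_f + \lambda w_m, c\,\sigma_w^2)} with `c`
#' chosen by `epi_offspring_variance`. Every individual gets one phenotype
#' \eqn{y = \mu + u + w + e}, \eqn{e \sim N(0, \sigma_e^2)}. Sexes in
#' descendant generations alternate within family so both sexes always
#' exist for the next generation.
#'
#' @param config an [sim_config()] object.
#' @return An object of class `epi_sim`: list with `pedigree`, true effect
#'   vectors `u` and `w`, residuals `e`, phenotypes `y`, `generation`, and
#'   the `config` used.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "epi_sim_config"))
  set.seed(config$seed)
  lam <- config$lambda
  c_w <- switch(config$epi_offspring_variance,
                model_consistent = 1 - 2 * lam^2,
                paper_as_written = (1 - lam)^2)

  n0 <- config$n_base
  n_off <- config$n_families * config$family_size
  n_total <- n0 + config$n_generations * n_off
  sire <- integer(n_total); dam <- integer(n_total)
  gen <- integer(n_total)
  male <- logical(n_total)
  u <- numeric(n_total); w <- numeric(n_total)

  male[seq_len(n0)] <- seq_len(n0) <= n0 / 2
  u[seq_len(n0)] <- rnorm(n0, 0, sqrt(config$sigma_u2))
  w[seq_len(n0)] <- rnorm(n0, 0, sqrt(config$sigma_w2))

  prev <- seq_len(n0)
  nxt <- n0
  for (g in seq_len(config$n_generations)) {
    males <- prev[male[prev]]
    females <- prev[!male[prev]]
    if (!length(males) || !length(females))
      stop("generation ", g - 1L, " cannot supply both a sire and a dam")
    fs <- sample(males, config$n_families, replace = TRUE)
    fd <- sample(females, config$n_families, replace = TRUE)
    off <- nxt + seq_len(n_off)
    sire[off] <- rep(fs, each = config$family_size)
    dam[off] <- rep(fd, each = config$family_size)
    gen[off] <- g
    male[off] <- rep_len(c(TRUE, FALSE), n_off)
    u[off] <- rnorm(n_off, 0.5 * (u[sire[off]] + u[dam[off]]),
                    sqrt(config$sigma_u2 / 2))
    w[off] <- rnorm(n_off, lam * (w[sire[off]] + w[dam[off]]),
                    sqrt(c_w * config$sigma_w2))
    prev <- off
    nxt <- nxt + n_off
  }
  e <- rnorm(n_total, 0, sqrt(config$sigma_e2))
  y <- config$mu + u + w + e
  ped <- pedigree(seq_len(n_total), sire, dam)
  structure(
    list(pedigree = ped, u = u, w = w, e = e, y = y, generation = gen,
         male = male, config = config),
    class = "epi_sim")
}

#' @exportS3Method base::print
print.epi_sim <- function(x, ...) {
  cat("Simulated population:", x$pedigree$n, "individuals (",
      x$config$n_base, "founders +", x$config$n_generations,
      "generations ), lambda =", x$config$lambda, "\n")
  invisible(x)
}

#' Enumerate relative pairs of a given class
#'
#' Extracts all index pairs (internal pedigree order) of a relationship
#' class: `parent_offspring` (each known parent with each offspring),
#' `full_sibs` (same known sire and dam), `half_sibs` (exactly one shared
#' known parent), and `uncle_nephew`, restricted to the case where one
#' member is a *full* sib of a parent of the other -- the configuration
#' whose expected epigenetic covariance is \eqn{2\lambda^3\sigma_w^2}.
#'
#' @param ped an [pedigree()] object.
#' @param relationship one of the four class names.
#' @return Two-column integer matrix of index pairs (possibly 0 rows).
#' @export
extract_relative_pairs <- function(ped,
                                   relationship = c("parent_offspring",
                                                    "full_sibs",
                                                    "half_sibs",
                                                    "uncle_nephew")) {
  stopifnot(inherits(ped, "epi_pedigree"))
  relationship <- match.arg(relationship)
  s <- ped$sire; d <- ped$dam
  idx <- seq_len(ped$n)
  pairs0 <- matrix(integer(0), 0, 2)

  sib_pairs <- function(groups) {
    res <- lapply(groups, function(g)
      if (length(g) >= 2) t(utils::combn(g, 2)) else NULL)
    out <- do.call(rbind, res)
    if (is.null(out)) pairs0 else out
  }
  full_sib_groups <- function() {
    ok <- s > 0L & d > 0L
    split(idx[ok], paste(s[ok], d[ok])[ok[ok]])
  }

  if (relationship == "parent_offspring") {
    out <- rbind(cbind(s[s > 0L], idx[s > 0L]),
                 cbind(d[d > 0L], idx[d > 0L]))
    return(if (nrow(out)) out else pairs0)
  }
  if (relationship == "full_sibs") {
    return(sib_pairs(full_sib_groups()))
  }
  if (relationship == "half_sibs") {
    # pairs sharing a sire, plus pairs sharing a dam, minus full sibs
    # (which appear in both lists)
    ps <- sib_pairs(split(idx[s > 0L], s[s > 0L]))
    pd <- sib_pairs(split(idx[d > 0L], d[d > 0L]))
    all <- rbind(ps, pd)
    if (!nrow(all)) return(pairs0)
    key <- paste(pmin(all[, 1], all[, 2]), pmax(all[, 1], all[, 2]))
    dup <- key[duplicated(key)]               # shared both parents
    out <- all[!duplicated(key) & !(key %in% dup), , drop = FALSE]
    return(if (nrow(out)) out else pairs0)
  }
  # uncle_nephew: x is a full sib of a parent of j
  fs <- sib_pairs(full_sib_groups())
  if (!nrow(fs)) return(pairs0)
  sib_of <- split(c(fs[, 2], fs[, 1]), c(fs[, 1], fs[, 2]))
  res <- list()
  for (j in idx) {
    uncles <- unique(c(
      if (s[j] > 0L) sib_of[[as.character(s[j])]],
      if (d[j] > 0L) sib_of[[as.character(d[j])]]))
    uncles <- setdiff(uncles, c(j, s[j], d[j]))
    if (length(uncles)) res[[length(res) + 1L]] <- cbind(uncles, j)
  }
  out <- do.call(rbind, res)
  if (is.null(out) || !nrow(out)) pairs0 else unname(out)
}

#' Write simulator output as plain-text files
#'
#' Writes `pedigree.txt` (read back by [read_pedigree()]),
#' `phenotypes.tsv` (columns `id`, `y`, `generation`; read back by
#' [cmd_fit()]) and `truth.tsv` (per-individual true `u`, `w`, `e` for
#' recovery scoring) under `dir`.
#'
#' @param sim an [simulate_population()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "epi_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pedigree = file.path(dir, "pedigree.txt"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_pedigree(sim$pedigree, paths["pedigree"])
  ord <- sim$pedigree$order_of_input       # input record -> internal row
  phen <- data.frame(id = sim$pedigree$label[ord], y = sim$y,
                     generation = sim$generation)
  write.table(phen, paths["phenotypes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- data.frame(id = sim$pedigree$label[ord], u = sim$u, w = sim$w,
                      e = sim$e)
  write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
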