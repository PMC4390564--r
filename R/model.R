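#' Specify an epigenetic animal model
#'
#' Describes the linear mixed model
#' \eqn{y = Xb + Z_1 u (+ Z_2 m) + \sum_k Z_k c_k + Z_1 w + e}:
#' fixed effects from a formula, an additive genetic effect `u` with
#' pedigree covariance \eqn{A\sigma_u^2} (optionally paired with a
#' correlated maternal genetic effect `m` under a 2x2 covariance matrix G),
#' any number of identity-structured random terms (permanent environment,
#' herd-year-season, ...), and a transgenerational epigenetic effect `w`
#' with covariance \eqn{T(\lambda)\sigma_w^2}.
#'
#' @param formula model formula for the response and fixed effects,
#'   evaluated in `data` (e.g. `y ~ 1` or `weight ~ sex + dam_age`). Use
#'   `~ 0` for a model with no fixed effects.
#' @param data data frame of phenotypic records.
#' @param id column name in `data` (or a vector of length `nrow(data)`)
#'   giving the pedigree individual of each record.
#' @param pedigree an [pedigree()] object.
#' @param genetic include the additive genetic term `u` (covariance A).
#' @param epigenetic include the epigenetic term `w` (covariance T).
#' @param maternal optional column name (or vector) giving the dam of each
#'   record; adds a maternal genetic effect `m` correlated with `u` through
#'   a 2x2 matrix G. Requires `genetic = TRUE`.
#' @param random character vector of column names in `data` to fit as
#'   identity-structured random effects with their own variances.
#' @return An object of class `epi_model_spec`.
#' @export
epi_model <- function(formula, data, id, pedigree,
                      genetic = TRUE, epigenetic = TRUE,
                      maternal = NULL, random = NULL) {
  stopifnot(inherits(pedigree, "epi_pedigree"))
  data <- as.data.frame(data)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.null(y)) stop("formula must have a response")
  y <- as.numeric(y)
  X <- stats::model.matrix(formula, mf)
  ndat <- length(y)

  resolve <- function(arg, what) {
    if (is.character(arg) && length(arg) == 1L && arg %in% names(data))
      arg <- data[[arg]]
    if (length(arg) != ndat)
      stop(what, " must name a column of 'data' or have one entry per record")
    as.character(arg)
  }
  id <- resolve(id, "'id'")
  id_pos <- match(id, pedigree$label)
  if (anyNA(id_pos))
    stop("record id(s) not in the pedigree: ",
         paste(unique(id[is.na(id_pos)]), collapse = ", "))

  mat_pos <- NULL
  if (!is.null(maternal)) {
    if (!genetic) stop("a maternal genetic effect requires genetic = TRUE")
    mat <- resolve(maternal, "'maternal'")
    mat_pos <- match(mat, pedigree$label)
    if (anyNA(mat_pos))
      stop("maternal id(s) not in the pedigree: ",
           paste(unique(mat[is.na(mat_pos)]), collapse = ", "))
  }

  iid <- list()
  for (nm in random) {
    f <- factor(resolve(nm, paste0("random term '", nm, "'")))
    iid[[nm]] <- list(label = nm, levels = levels(f),
                      pos = as.integer(f), size = nlevels(f))
  }

  structure(
    list(y = y, X = X, id_pos = id_pos, mat_pos = mat_pos, iid = iid,
         pedigree = pedigree, genetic = genetic, epigenetic = epigenetic,
         formula = formula, ndat = ndat),
    class = "epi_model_spec")
}

#' @exportS3Method base::print
print.epi_model_spec <- function(x, ...) {
  terms <- c(if (ncol(x$X)) paste0("fixed[", ncol(x$X), "]"),
             if (x$genetic && is.null(x$mat_pos)) "u (A)",
             if (!is.null(x$mat_pos)) "u + m (A, correlated)",
             names(x$iid),
             if (x$epigenetic) "w (T)")
  cat("Epigenetic animal model:", x$ndat, "records,",
      x$pedigree$n, "pedigree individuals\n  terms:",
      paste(terms, collapse = ", "), "\n")
  invisible(x)
}

#' Prior specification for variance components
#'
#' Every variance has a scaled inverse chi-square prior with scale `s2` and
#' degrees of belief `n`; a draw from the full conditional is
#' `(quadratic + s2) / rchisq(count + n)`. The default `(s2 = 0, n = -2)`
#' is the flat (bounded-uniform) prior on the variance itself. For a
#' correlated direct/maternal pair the 2x2 matrix G has an inverse-Wishart
#' prior with degrees of freedom `n_G` and scale `G0`; `n_G = -3`,
#' `G0 = 0` is the flat choice. The prior for `lambda` is fixed at
#' uniform(0, 0.5).
#'
#' @param sigma_u2,sigma_w2,sigma_e2 numeric `c(s2, n)` pairs.
#' @param random named list of `c(s2, n)` pairs for identity-structured
#'   terms; terms not named get the flat default.
#' @param n_G,G0 inverse-Wishart hyperparameters for G.
#' @return An object of class `epi_prior_spec`.
#' @export
prior_spec <- function(sigma_u2 = c(0, -2), sigma_w2 = c(0, -2),
                       sigma_e2 = c(0, -2), random = list(),
                       n_G = -3, G0 = matrix(0, 2, 2)) {
  chk <- function(p, nm) {
    if (length(p) != 2 || !is.numeric(p) || p[1] < 0)
      stop("prior for ", nm, " must be c(s2 >= 0, n)")
    as.numeric(p)
  }
  structure(
    list(sigma_u2 = chk(sigma_u2, "sigma_u2"),
         sigma_w2 = chk(sigma_w2, "sigma_w2"),
         sigma_e2 = chk(sigma_e2, "sigma_e2"),
         random = lapply(random, chk, nm = "a random term"),
         n_G = as.numeric(n_G), G0 = G0),
    class = "epi_prior_spec")
}

#' Gibbs sampler configuration
#'
#' Chain-protocol settings. The defaults (100,000 cycles, 20,000 burn-in,
#' thinning 5) are desk-scale; production analyses of large pedigrees use
#' chains an order of magnitude longer (e.g. 1,250,000 cycles with 250,000
#' discarded).
#'
#' @param n_iter total Gibbs cycles.
#' @param burn_in cycles discarded before storage (`< n_iter`).
#' @param thin store every `thin`-th post-burn-in cycle (>= 1).
#' @param seed integer seed for the chain (`set.seed`); `NULL` leaves the
#'   RNG state untouched.
#' @param lambda_update `"paper_tn"` draws lambda from its truncated-normal
#'   full conditional with the variance factors evaluated at the current
#'   lambda; `"metropolis_exact"` uses that TN as a proposal and
#'   accepts/rejects against the exact conditional, which keeps the
#'   lambda-dependence of the residual epigenetic variances.
#' @param store_effects store the full location-effect vector per kept
#'   cycle (memory: `n_stored x dim`).
#' @param store_fitted store the fitted value of every record per kept
#'   cycle (needed by [log_cpo()]).
#' @return An object of class `epi_gibbs_config`.
#' @export
gibbs_config <- function(n_iter = 100000, burn_in = 20000, thin = 5,
                         seed = NULL,
                         lambda_update = c("paper_tn", "metropolis_exact"),
                         store_effects = FALSE, store_fitted = FALSE) {
  lambda_update <- match.arg(lambda_update)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  structure(
    list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
         thin = as.integer(thin), seed = seed,
         lambda_update = lambda_update,
         store_effects = isTRUE(store_effects),
         store_fitted = isTRUE(store_fitted)),
    class = "epi_gibbs_config")
}

# ---------------------------------------------------------------------------
# Equation layout shared by build_mme() and the sampler plan.
# Order: fixed effects, u (, m), identity-structured terms, w.
model_layout <- function(spec) {
  n_ind <- spec$pedigree$n
  p <- ncol(spec$X)
  off <- p
  blocks <- list()
  if (spec$genetic) {
    blocks$u <- c(off = off, size = n_ind); off <- off + n_ind
    if (!is.null(spec$mat_pos)) {
      blocks$m <- c(off = off, size = n_ind); off <- off + n_ind
    }
  }
  for (nm in names(spec$iid)) {
    blocks[[nm]] <- c(off = off, size = spec$iid[[nm]]$size)
    off <- off + spec$iid[[nm]]$size
  }
  if (spec$epigenetic) {
    blocks$w <- c(off = off, size = n_ind); off <- off + n_ind
  }
  list(p = p, dim = off, blocks = blocks, n_ind = n_ind)
}

# Overall sparse incidence matrix W = [X | Z_u | Z_m | Z_k ... | Z_w].
incidence_matrix <- function(spec, layout) {
  ndat <- spec$ndat
  rows <- list(); cols <- list(); vals <- list()
  if (layout$p > 0) {
    rows[[1]] <- rep(seq_len(ndat), layout$p)
    cols[[1]] <- rep(seq_len(layout$p), each = ndat)
    vals[[1]] <- as.numeric(spec$X)
  }
  add <- function(block, pos) {
    rows[[length(rows) + 1L]] <<- seq_len(ndat)
    cols[[length(cols) + 1L]] <<- layout$blocks[[block]]["off"] + pos
    vals[[length(vals) + 1L]] <<- rep(1, ndat)
  }
  if (spec$genetic) add("u", spec$id_pos)
  if (!is.null(spec$mat_pos)) add("m", spec$mat_pos)
  for (nm in names(spec$iid)) add(nm, spec$iid[[nm]]$pos)
  if (spec$epigenetic) add("w", spec$id_pos)
  W <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols),
                            x = unlist(vals),
                            dims = c(ndat, layout$dim))
  Matrix::drop0(W)
}

# Place a symmetric sparse matrix into a dim x dim matrix at (roff, coff).
embed_at <- function(M, dim, roff, coff) {
  Tm <- as(as(M, "generalMatrix"), "TsparseMatrix")
  Matrix::sparseMatrix(i = Tm@i + 1L + roff, j = Tm@j + 1L + coff,
                       x = Tm@x, dims = c(dim, dim))
}

#' Assemble the mixed-model equations
#'
#' Builds the coefficient matrix `C` and right-hand side `r` of the system
#' `C s = r` at fixed values of the variance components:
#' `C = W'W + A^-1 alpha` (u block) `+ T^-1(lambda) psi` (w block)
#' `+ I sigma_e2/sigma_k2` (identity-structured blocks), with
#' `alpha = sigma_e2/sigma_u2`, `psi = sigma_e2/sigma_w2`; for a correlated
#' direct/maternal pair the u/m blocks receive
#' `A^-1 (G^-1)_{jk} sigma_e2`. `r = W'y`.
#'
#' @param spec an [epi_model()] specification.
#' @param variances named list with the components the model uses:
#'   `sigma_e2`, and `sigma_u2` (or `G`, a 2x2 matrix, when a maternal term
#'   is present), `sigma_w2` with `lambda`, and one entry per
#'   identity-structured term (by its term name).
#' @return A list of class `epi_mme` with `C` (sparse), `r`, `s` (initial
#'   zeros), `layout`, and the ratios used.
#' @export
build_mme <- function(spec, variances) {
  stopifnot(inherits(spec, "epi_model_spec"))
  layout <- model_layout(spec)
  W <- incidence_matrix(spec, layout)
  sige2 <- variances$sigma_e2
  if (is.null(sige2) || sige2 <= 0) stop("sigma_e2 must be positive")
  C <- as(as(Matrix::crossprod(W), "generalMatrix"), "CsparseMatrix")
  n_ind <- layout$n_ind
  if (spec$genetic) {
    Ainv <- build_A_inverse(spec$pedigree)
    uoff <- layout$blocks$u["off"]
    if (is.null(spec$mat_pos)) {
      if (is.null(variances$sigma_u2) || variances$sigma_u2 <= 0)
        stop("sigma_u2 must be positive for the genetic term")
      C <- C + embed_at(Ainv, layout$dim, uoff, uoff) *
        (sige2 / variances$sigma_u2)
    } else {
      G <- variances$G
      if (is.null(G) || any(dim(G) != 2) || det(G) <= 0)
        stop("a positive definite 2x2 G is required for the maternal pair")
      Gi <- solve(G)
      moff <- layout$blocks$m["off"]
      C <- C +
        embed_at(Ainv, layout$dim, uoff, uoff) * (sige2 * Gi[1, 1]) +
        embed_at(Ainv, layout$dim, uoff, moff) * (sige2 * Gi[1, 2]) +
        embed_at(Ainv, layout$dim, moff, uoff) * (sige2 * Gi[1, 2]) +
        embed_at(Ainv, layout$dim, moff, moff) * (sige2 * Gi[2, 2])
    }
  }
  for (nm in names(spec$iid)) {
    sk <- variances[[nm]]
    if (is.null(sk) || sk <= 0)
      stop("a positive variance is required for random term '", nm, "'")
    b <- layout$blocks[[nm]]
    C <- C + Matrix::sparseMatrix(i = b["off"] + seq_len(b["size"]),
                                  j = b["off"] + seq_len(b["size"]),
                                  x = sige2 / sk,
                                  dims = c(layout$dim, layout$dim))
  }
  if (spec$epigenetic) {
    if (is.null(variances$sigma_w2) || variances$sigma_w2 <= 0)
      stop("sigma_w2 must be positive for the epigenetic term")
    if (is.null(variances$lambda)) stop("lambda is required with sigma_w2")
    Tinv <- build_T_inverse(spec$pedigree, variances$lambda)
    woff <- layout$blocks$w["off"]
    C <- C + embed_at(Tinv, layout$dim, woff, woff) *
      (sige2 / variances$sigma_w2)
  }
  structure(
    list(C = as(as(C, "generalMatrix"), "CsparseMatrix"),
         r = as.numeric(Matrix::crossprod(W, spec$y)),
         s = numeric(layout$dim), W = W, layout = layout,
         sigma_e2 = sige2),
    class = "epi_mme")
}

# ---------------------------------------------------------------------------
# Sampler plan: fixed sparsity pattern + per-component value vectors, in the
# form the compiled engine consumes (0-based indices throughout).
gibbs_plan <- function(spec) {
  layout <- model_layout(spec)
  ped <- spec$pedigree
  n_ind <- layout$n_ind
  dim <- layout$dim
  W <- incidence_matrix(spec, layout)
  Cdata <- as(as(Matrix::crossprod(W), "generalMatrix"), "CsparseMatrix")

  trip <- function(M) {
    Tm <- as(as(M, "generalMatrix"), "TsparseMatrix")
    list(i = Tm@i, j = Tm@j, x = Tm@x)       # 0-based
  }
  key_of <- function(i, j) as.numeric(i) + as.numeric(dim) * as.numeric(j)

  pattern <- abs(Cdata)
  comp <- list(gen = NULL, pair = NULL, epi = NULL)
  At <- NULL
  if (spec$genetic) At <- trip(build_A_inverse(ped))

  add_pattern <- function(i, j, dims = dim) {
    Matrix::sparseMatrix(i = i + 1L, j = j + 1L, x = rep(1, length(i)),
                         dims = c(dims, dims))
  }

  uoff <- if (spec$genetic) unname(layout$blocks$u["off"]) else 0L
  moff <- if (!is.null(spec$mat_pos)) unname(layout$blocks$m["off"]) else 0L
  if (spec$genetic && is.null(spec$mat_pos)) {
    pattern <- pattern + add_pattern(At$i + uoff, At$j + uoff)
  } else if (!is.null(spec$mat_pos)) {
    pattern <- pattern + add_pattern(At$i + uoff, At$j + uoff) +
      add_pattern(At$i + uoff, At$j + moff) +
      add_pattern(At$i + moff, At$j + uoff) +
      add_pattern(At$i + moff, At$j + moff)
  }
  for (nm in names(spec$iid)) {
    b <- layout$blocks[[nm]]
    dd <- unname(b["off"]) + seq_len(b["size"]) - 1L
    pattern <- pattern + add_pattern(dd, dd)
  }

  # T^-1 structure: per-individual contribution positions, by coefficient
  # type. bd/bl/bq: both-parent diag, linear (-lambda d) and quadratic
  # (lambda^2 d) positions; od/ol/oq: one-parent analogues; f: founder diag.
  epi <- NULL
  if (spec$epigenetic) {
    woff <- unname(layout$blocks$w["off"])
    s <- ped$sire; d <- ped$dam
    both <- which(s > 0L & d > 0L)
    one <- which(xor(s > 0L, d > 0L))
    par1 <- ifelse(ped$sire[one] > 0L, ped$sire[one], ped$dam[one])
    fou <- which(s == 0L & d == 0L)
    g <- function(v) woff + v - 1L                  # 0-based global index
    type_keys <- list(
      bd = key_of(g(both), g(both)),
      bl = c(key_of(g(both), g(s[both])), key_of(g(s[both]), g(both)),
             key_of(g(both), g(d[both])), key_of(g(d[both]), g(both))),
      bq = c(key_of(g(s[both]), g(s[both])), key_of(g(d[both]), g(d[both])),
             key_of(g(s[both]), g(d[both])), key_of(g(d[both]), g(s[both]))),
      od = key_of(g(one), g(one)),
      ol = c(key_of(g(one), g(par1)), key_of(g(par1), g(one))),
      oq = key_of(g(par1), g(par1)),
      f  = key_of(g(fou), g(fou)))
    keysT <- sort(unique(unlist(type_keys)))
    base_vec <- function(keys) {
      out <- numeric(length(keysT))
      if (length(keys)) {
        tab <- rowsum(rep(1, length(keys)), keys)
        out[match(as.numeric(rownames(tab)), keysT)] <- tab[, 1]
      }
      out
    }
    iT <- as.integer(keysT %% dim)
    jT <- as.integer(keysT %/% dim)
    pattern <- pattern + add_pattern(iT, jT)
    epi <- list(keysT = keysT,
                bbd = base_vec(type_keys$bd), bbl = base_vec(type_keys$bl),
                bbq = base_vec(type_keys$bq), bod = base_vec(type_keys$od),
                bol = base_vec(type_keys$ol), boq = base_vec(type_keys$oq),
                bf = base_vec(type_keys$f),
                sire = ped$sire, dam = ped$dam, w_off = woff)
  }

  # union pattern -> CSC arrays and key lookup
  U <- as(as(Matrix::drop0(pattern), "generalMatrix"), "CsparseMatrix")
  Up <- U@p; Ui <- U@i
  Ujj <- rep.int(seq_len(dim) - 1L, diff(Up))
  keysU <- key_of(Ui, Ujj)
  locate <- function(keys) {
    idx <- match(keys, keysU)
    if (anyNA(idx)) stop("internal error: pattern union is incomplete")
    idx - 1L
  }
  place <- function(tr, roff, coff) {
    keys <- key_of(tr$i + roff, tr$j + coff)
    idx <- locate(keys)
    list(idx = idx, val = tr$x, qi = tr$i + roff, qj = tr$j + coff)
  }

  Vdata <- numeric(length(keysU))
  dt <- trip(Cdata)
  Vdata[locate(key_of(dt$i, dt$j)) + 1L] <- dt$x

  gen <- NULL; pair <- NULL
  if (spec$genetic && is.null(spec$mat_pos)) {
    gen <- place(At, uoff, uoff)
  } else if (!is.null(spec$mat_pos)) {
    puu <- place(At, uoff, uoff)
    pum1 <- place(At, uoff, moff)
    pum2 <- place(At, moff, uoff)
    pmm <- place(At, moff, moff)
    pair <- list(idx_uu = puu$idx, val_uu = puu$val,
                 qi_uu = puu$qi, qj_uu = puu$qj,
                 idx_um = c(pum1$idx, pum2$idx),
                 val_um = c(pum1$val, pum2$val),
                 qi_um = c(pum1$qi, pum2$qi),
                 qj_um = c(pum1$qj, pum2$qj),
                 idx_mm = pmm$idx, val_mm = pmm$val,
                 qi_mm = pmm$qi, qj_mm = pmm$qj)
  }
  iid_comps <- list()
  for (nm in names(spec$iid)) {
    b <- layout$blocks[[nm]]
    dd <- unname(b["off"]) + seq_len(b["size"]) - 1L
    iid_comps[[nm]] <- list(idx = locate(key_of(dd, dd)),
                            off = unname(b["off"]),
                            size = unname(b["size"]))
  }
  if (!is.null(epi)) {
    idxT <- locate(epi$keysT)
    epi <- c(epi[c("bbd", "bbl", "bbq", "bod", "bol", "boq", "bf",
                   "sire", "dam", "w_off")],
             list(idx = idxT,
                  qi = as.integer(epi$keysT %% dim),
                  qj = as.integer(epi$keysT %/% dim)))
  }

  Wr <- as(W, "RsparseMatrix")
  list(Cp = Up, Ci = Ui, Vdata = Vdata,
       r = as.numeric(Matrix::crossprod(W, spec$y)), y = spec$y,
       Wp = Wr@p, Wj = Wr@j, Wx = Wr@x,
       n_ind = n_ind, dim = dim, layout = layout,
       gen = gen, pair = pair, iid = iid_comps, epi = epi)
}

# Reconstruct the coefficient matrix a plan implies at given variances;
# used in tests to confirm the engine's assembly against build_mme().
plan_C <- function(plan, variances) {
  Cv <- plan$Vdata
  sige2 <- variances$sigma_e2
  if (!is.null(plan$gen)) {
    Cv[plan$gen$idx + 1L] <- Cv[plan$gen$idx + 1L] +
      (sige2 / variances$sigma_u2) * plan$gen$val
  }
  if (!is.null(plan$pair)) {
    Gi <- solve(variances$G)
    Cv[plan$pair$idx_uu + 1L] <- Cv[plan$pair$idx_uu + 1L] +
      sige2 * Gi[1, 1] * plan$pair$val_uu
    Cv[plan$pair$idx_um + 1L] <- Cv[plan$pair$idx_um + 1L] +
      sige2 * Gi[1, 2] * plan$pair$val_um
    Cv[plan$pair$idx_mm + 1L] <- Cv[plan$pair$idx_mm + 1L] +
      sige2 * Gi[2, 2] * plan$pair$val_mm
  }
  for (nm in names(plan$iid)) {
    comp <- plan$iid[[nm]]
    Cv[comp$idx + 1L] <- Cv[comp$idx + 1L] + sige2 / variances[[nm]]
  }
  if (!is.null(plan$epi)) {
    valT <- cpp_tinv_values(variances$lambda, plan$epi$bbd, plan$epi$bbl,
                            plan$epi$bbq, plan$epi$bod, plan$epi$bol,
                            plan$epi$boq, plan$epi$bf)
    Cv[plan$epi$idx + 1L] <- Cv[plan$epi$idx + 1L] +
      (sige2 / variances$sigma_w2) * valT
  }
  methods::new("dgCMatrix", p = plan$Cp, i = plan$Ci, x = Cv,
               Dim = c(plan$dim, plan$dim))
}

#' Run the Gibbs sampler
#'
#' Iterates, in fixed order: a single-site sweep over all location effects,
#' the lambda update (with the sparse T^-1 values refreshed from the new
#' lambda; the sparsity pattern is pedigree-only and built once), then the
#' variance-component updates from their scaled inverse chi-square (and,
#' for a direct/maternal pair, inverse-Wishart) full conditionals. Draws of
#' every scalar unknown after burn-in and thinning are returned, together
#' with derived chains for the reset coefficient `v = 1 - 2 lambda`, the
#' transmission coefficient `1 - v`, and the variance ratios (h2, gamma2,
#' and m2 when a maternal term is present) computed per stored cycle.
#'
#' @param spec an [epi_model()] specification.
#' @param priors an [prior_spec()] object.
#' @param config an [gibbs_config()] object.
#' @param init optional list of starting values (`s`, `lambda`, `sigma_u2`
#'   or `G`, `sigma_w2`, `sigma_e2`, `sigma_iid`); also accepts the `state`
#'   element of a previous run to continue a chain.
#' @return An object of class `epi_samples`: list with `draws` (matrix,
#'   stored cycles x parameters), optional `effects` and `fitted` matrices,
#'   the final `state`, and metadata.
#' @export
run_gibbs <- function(spec, priors = prior_spec(), config = gibbs_config(),
                      init = NULL) {
  stopifnot(inherits(spec, "epi_model_spec"),
            inherits(priors, "epi_prior_spec"),
            inherits(config, "epi_gibbs_config"))
  layout <- model_layout(spec)
  n_ind <- layout$n_ind

  if (spec$epigenetic &&
      all(spec$pedigree$sire == 0L & spec$pedigree$dam == 0L))
    warning("pedigree has no parent-offspring links: lambda is ",
            "unidentifiable and will be drawn from its prior")

  # posterior degrees of freedom must be positive for every active term
  chk_df <- function(count, n, nm) {
    if (count + n <= 0)
      stop("posterior degrees of freedom for ", nm,
           " are not positive (count ", count, " + prior n ", n, ")")
  }
  chk_df(spec$ndat, priors$sigma_e2[2], "sigma_e2")
  if (spec$genetic && is.null(spec$mat_pos))
    chk_df(n_ind, priors$sigma_u2[2], "sigma_u2")
  if (!is.null(spec$mat_pos) && n_ind + priors$n_G <= 1)
    stop("posterior degrees of freedom for G must exceed 1")
  if (spec$epigenetic) chk_df(n_ind, priors$sigma_w2[2], "sigma_w2")
  iid_s2 <- numeric(0); iid_n <- numeric(0)
  for (nm in names(spec$iid)) {
    pr <- priors$random[[nm]]
    if (is.null(pr)) pr <- c(0, -2)
    chk_df(spec$iid[[nm]]$size, pr[2], nm)
    iid_s2 <- c(iid_s2, pr[1]); iid_n <- c(iid_n, pr[2])
  }

  plan <- gibbs_plan(spec)
  if (!is.null(config$seed)) set.seed(config$seed)

  vy <- stats::var(spec$y)
  n_var_terms <- spec$genetic + (!is.null(spec$mat_pos)) +
    length(spec$iid) + spec$epigenetic + 1
  v0 <- vy / n_var_terms
  default_init <- list(
    s = numeric(layout$dim), lambda = 0.25, sigma_u2 = v0,
    G = diag(c(v0, v0)), sigma_w2 = v0, sigma_e2 = v0,
    sigma_iid = rep(v0, length(spec$iid)))
  if (!is.null(init)) {
    for (nm in names(init)) default_init[[nm]] <- init[[nm]]
  }

  pr <- list(s2_e = priors$sigma_e2[1], n_e = priors$sigma_e2[2],
             s2_u = priors$sigma_u2[1], n_u = priors$sigma_u2[2],
             s2_w = priors$sigma_w2[1], n_w = priors$sigma_w2[2],
             n_G = priors$n_G, G0 = priors$G0,
             s2_iid = iid_s2, n_iid = iid_n)
  cfg <- list(n_iter = config$n_iter, burn_in = config$burn_in,
              thin = config$thin,
              lambda_mode = if (config$lambda_update == "paper_tn") 0L else 1L,
              store_effects = config$store_effects,
              store_fitted = config$store_fitted)

  res <- cpp_run_gibbs(plan, pr, cfg, default_init)

  cols <- c(if (spec$genetic && is.null(spec$mat_pos)) "sigma_u2",
            if (!is.null(spec$mat_pos)) c("sigma_u2", "sigma_m2", "sigma_um"),
            if (length(spec$iid)) paste0("sigma2_", names(spec$iid)),
            if (spec$epigenetic) c("sigma_w2", "lambda"),
            "sigma_e2")
  draws <- res$draws
  colnames(draws) <- cols

  # derived chains, computed per stored cycle (ratio-of-draws convention)
  var_cols <- setdiff(cols, c("lambda", "sigma_um"))
  tot <- rowSums(draws[, var_cols, drop = FALSE])
  extra <- NULL
  if (spec$epigenetic) {
    lam <- draws[, "lambda"]
    extra <- cbind(v = 1 - 2 * lam, transmission = 2 * lam,
                   gamma2 = draws[, "sigma_w2"] / tot)
  }
  if ("sigma_u2" %in% cols)
    extra <- cbind(extra, h2 = draws[, "sigma_u2"] / tot)
  if ("sigma_m2" %in% cols)
    extra <- cbind(extra, m2 = draws[, "sigma_m2"] / tot)
  if (!is.null(extra)) draws <- cbind(draws, extra)

  structure(
    list(draws = draws, effects = res$effects, fitted = res$fitted,
         state = res$state, n_stored = res$n_stored,
         lambda_acceptance = res$lambda_acceptance,
         layout = layout, config = config,
         y = spec$y, terms = cols),
    class = "epi_samples")
}

#' @exportS3Method base::print
print.epi_samples <- function(x, ...) {
  cat("Posterior samples:", nrow(x$draws), "stored cycles of",
    x$config$n_iter, "(burn-in", x$config$burn_in,
    ", thin", x$config$thin, ")\n")
  print(posterior_summary(x), digits = 4)
  invisible(x)
}
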