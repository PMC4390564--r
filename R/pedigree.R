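#' Construct and validate a pedigree
#'
#' A pedigree is a set of individual--sire--dam triples. Unknown parents are
#' coded 0 (or `NA`). The constructor validates referential integrity
#' (every named parent must itself be an individual), rejects duplicate ids
#' and self-ancestry (cycles), and reorders individuals topologically so
#' that parents always precede their offspring -- the traversal order
#' required by Henderson's rules for the inverse numerator relationship
#' matrix and by the analogous one-pass rules for the inverse epigenetic
#' relationship matrix.
#'
#' @param id vector of individual labels (coerced to character).
#' @param sire,dam vectors of parent labels; `0`, `"0"` or `NA` = unknown.
#' @return An object of class `epi_pedigree`: a list with elements
#'   `label` (original labels in internal order), `sire`, `dam` (integer
#'   indices into internal order, 0 = unknown), `n`, and `order_of_input`
#'   (position of each input record in the internal order).
#' @examples
#' ped <- pedigree(id = c(1, 2, 3), sire = c(0, 0, 1), dam = c(0, 0, 2))
#' ped$n
#' @export
pedigree <- function(id, sire, dam) {
  id <- as.character(id)
  sire <- as.character(sire)
  dam <- as.character(dam)
  sire[is.na(sire)] <- "0"
  dam[is.na(dam)] <- "0"
  n <- length(id)
  if (length(sire) != n || length(dam) != n)
    stop("id, sire and dam must have equal length")
  if (anyDuplicated(id))
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(id == "0")) stop("'0' is reserved for unknown parents")
  si <- match(sire, id)
  di <- match(dam, id)
  bad_s <- sire != "0" & is.na(si)
  bad_d <- dam != "0" & is.na(di)
  if (any(bad_s | bad_d))
    stop("parent id(s) referenced but never declared as individuals: ",
         paste(unique(c(sire[bad_s], dam[bad_d])), collapse = ", "))
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L
  if (any(si == seq_len(n)) || any(di == seq_len(n)))
    stop("an individual cannot be its own parent")

  ord <- topo_order(si, di)          # errors on cycles
  pos <- integer(n)
  pos[ord] <- seq_len(n)             # input index -> internal position
  remap <- function(p) {
    out <- integer(length(p))
    nz <- p != 0L
    out[nz] <- pos[p[nz]]
    out
  }
  structure(
    list(label = id[ord],
         sire  = remap(si[ord]),
         dam   = remap(di[ord]),
         n = n,
         order_of_input = pos),
    class = "epi_pedigree")
}

# Kahn's algorithm over the parent -> offspring edges; detects cycles.
# Input order is preserved when it is already parents-first.
topo_order <- function(sire, dam) {
  n <- length(sire)
  ii <- seq_len(n)
  if (all(sire < ii) && all(dam < ii)) return(ii)
  indeg <- (sire != 0L) + (dam != 0L)          # one unit per parent edge
  par <- c(sire, dam); child <- c(ii, ii)
  keep <- par != 0L
  kids <- split(child[keep], factor(par[keep], levels = ii))
  out <- integer(n)
  queue <- which(indeg == 0L)
  tail <- length(queue)
  out[seq_len(tail)] <- queue
  head <- 1L
  while (head <= tail) {
    v <- out[head]; head <- head + 1L
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) { tail <- tail + 1L; out[tail] <- k }
    }
  }
  if (tail != n)
    stop("pedigree contains a cycle (an individual is its own ancestor)")
  out
}

#' @exportS3Method base::print
print.epi_pedigree <- function(x, ...) {
  n_both <- sum(x$sire > 0L & x$dam > 0L)
  n_one  <- sum(xor(x$sire > 0L, x$dam > 0L))
  cat("Pedigree with", x$n, "individuals:",
      x$n - n_both - n_one, "founders,",
      n_one, "with one known parent,",
      n_both, "with both parents known\n")
  invisible(x)
}

#' @export
as.data.frame.epi_pedigree <- function(x, ...) {
  data.frame(id = x$label,
             sire = ifelse(x$sire == 0L, "0", x$label[pmax(x$sire, 1L)]),
             dam  = ifelse(x$dam == 0L, "0", x$label[pmax(x$dam, 1L)]),
             stringsAsFactors = FALSE)
}

#' Read a pedigree file
#'
#' Reads a plain-text pedigree with columns `id sire dam` (extra columns are
#' ignored). Fields may be whitespace- or comma-delimited (auto-detected);
#' lines starting with `#` are treated as comments/header. `0` denotes an
#' unknown parent.
#'
#' @param path path to the pedigree file.
#' @return An [pedigree()] object (validated, topologically ordered).
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no pedigree records in ", path)
  sep <- if (any(grepl(",", lines, fixed = TRUE))) "," else ""
  dat <- read.table(text = lines, sep = sep, header = FALSE,
                    colClasses = "character", strip.white = TRUE)
  if (ncol(dat) < 3)
    stop("pedigree file must have at least 3 columns (id, sire, dam)")
  pedigree(dat[[1]], dat[[2]], dat[[3]])
}

#' Write a pedigree file
#'
#' Inverse of [read_pedigree()]: whitespace-delimited `id sire dam` rows in
#' topological order, with a `#` header line.
#'
#' @param ped an [pedigree()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "epi_pedigree"))
  df <- as.data.frame(ped)
  writeLines(c("# id sire dam",
               paste(df$id, df$sire, df$dam)), path)
  invisible(path)
}

#' Inverse numerator relationship matrix by Henderson's rules
#'
#' Builds the sparse inverse of the additive (numerator) relationship
#' matrix A without inbreeding accounting. Per individual: both parents
#' known -- add 2 to (i,i), -1 to (i,sire) and (i,dam), 1/2 to (sire,sire),
#' (dam,dam) and (sire,dam); one parent known -- add 4/3, -2/3 and 1/3; a
#' founder contributes 1 to its diagonal.
#'
#' @param ped an [pedigree()] object.
#' @return A symmetric sparse [Matrix::Matrix] (class `dsCMatrix`) of
#'   dimension `ped$n`.
#' @export
build_A_inverse <- function(ped) {
  stopifnot(inherits(ped, "epi_pedigree"))
  relationship_inverse(ped, rule = "A")
}

# Shared one-pass assembly of A^-1 (rule = "A") and T^-1 (rule = "T").
# Each non-founder i contributes the rank-1 block
#   d^-1 (e_i - c e_f - c e_m)(e_i - c e_f - c e_m)'
# with c = 1/2, d = 1/2 (both) or 3/4 (one) for A, and c = lambda,
# d = 1 - 2 lambda^2 (both) or 1 - lambda^2 (one) for T; founders add 1.
relationship_inverse <- function(ped, rule = c("A", "T"), lambda = NULL) {
  rule <- match.arg(rule)
  n <- ped$n
  s <- ped$sire
  d <- ped$dam
  if (rule == "A") {
    cc <- 0.5
    d_both <- 0.5
    d_one <- 0.75
  } else {
    cc <- lambda
    d_both <- 1 - 2 * lambda^2
    d_one <- 1 - lambda^2
  }
  idx <- seq_len(n)
  both <- which(s > 0L & d > 0L)
  s_only <- which(s > 0L & d == 0L)
  d_only <- which(s == 0L & d > 0L)
  one <- c(s_only, d_only)
  par1 <- c(s[s_only], d[d_only])

  ii <- jj <- xx <- list()
  # every individual's own diagonal
  dii <- rep(1, n)
  dii[both] <- 1 / d_both
  dii[one] <- 1 / d_one
  ii[[1]] <- idx; jj[[1]] <- idx; xx[[1]] <- dii
  if (length(both)) {
    kb <- 1 / d_both
    f <- s[both]; m <- d[both]
    ii[[2]] <- c(both, f, both, m, f, m, f, m)
    jj[[2]] <- c(f, both, m, both, f, m, m, f)
    xx[[2]] <- c(rep(-cc * kb, 4 * length(both)),
                 rep(cc^2 * kb, 4 * length(both)))
  }
  if (length(one)) {
    ko <- 1 / d_one
    ii[[3]] <- c(one, par1, par1)
    jj[[3]] <- c(par1, one, par1)
    xx[[3]] <- c(rep(-cc * ko, 2 * length(one)), rep(cc^2 * ko, length(one)))
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  Matrix::forceSymmetric(M, uplo = "U")
}

#' Dense numerator relationship matrix by the tabular method
#'
#' Recursive (tabular) construction of A for small pedigrees:
#' `a_ii = 1 + a(sire,dam)/2` and `a_ij = (a(j,sire) + a(j,dam))/2` for
#' `j < i` in topological order. Intended as an exact reference for tests
#' and teaching; refuses pedigrees larger than `max_n` to guard against the
#' dense \eqn{O(n^2)} blow-up.
#'
#' @param ped an [pedigree()] object.
#' @param max_n refuse pedigrees with more individuals than this.
#' @return Dense symmetric `n x n` matrix A.
#' @export
build_A_tabular <- function(ped, max_n = 2000) {
  stopifnot(inherits(ped, "epi_pedigree"))
  n <- ped$n
  if (n > max_n)
    stop("pedigree has ", n, " individuals; dense A is capped at max_n = ",
         max_n)
  A <- diag(n)
  s <- ped$sire
  d <- ped$dam
  for (i in seq_len(n)) {
    if (s[i] > 0L && d[i] > 0L) A[i, i] <- 1 + 0.5 * A[s[i], d[i]]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s[i] > 0L) row <- row + A[j, s[i]]
      if (d[i] > 0L) row <- row + A[j, d[i]]
      A[i, j] <- A[j, i] <- 0.5 * row
    }
  }
  A
}
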