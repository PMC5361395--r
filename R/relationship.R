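#' Pedigree additive relationship matrix (tabular method)
#'
#' Standard recursive (tabular) construction: for individual `i` with parents
#' `s`, `d` (oldest first), `A[i,j] = (A[s,j] + A[d,j]) / 2` for any older
#' `j`, and `A[i,i] = 1 + A[s,d] / 2`; an unknown parent contributes zero.
#'
#' @param ped data frame with columns `id`, `sire`, `dam` (0 or NA =
#'   unknown parent), ordered so that parents precede offspring.
#' @return symmetric matrix with `id` dimnames; diagonal `1 + F`.
#' @export
pedigree_A <- function(ped) {
  ped <- normalize_pedigree(ped)
  n <- nrow(ped)
  si <- ped$si; di <- ped$di
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + A[s, j]
      if (!is.na(d)) row <- row + A[d, j]
      row <- row / 2
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
  }
  A
}

# validate/annotate a pedigree: unique ids, parents precede offspring
normalize_pedigree <- function(ped) {
  ped <- as.data.frame(ped)
  if (!all(c("id", "sire", "dam") %in% names(ped)))
    stop("pedigree needs columns 'id', 'sire', 'dam'")
  id <- as.character(ped$id)
  if (anyDuplicated(id)) stop("pedigree ids must be unique")
  unknown <- function(x) is.na(x) | x == 0 | x == "0"
  si <- match(as.character(ped$sire), id)
  di <- match(as.character(ped$dam), id)
  si[unknown(ped$sire)] <- NA_integer_
  di[unknown(ped$dam)] <- NA_integer_
  if (any(!unknown(ped$sire) & is.na(si)) ||
      any(!unknown(ped$dam) & is.na(di)))
    stop("pedigree references a parent id that is not listed")
  i <- seq_len(nrow(ped))
  if (any(si >= i, na.rm = TRUE) || any(di >= i, na.rm = TRUE))
    stop("pedigree is not ordered oldest to youngest (or is cyclic)")
  data.frame(id = id, si = si, di = di, stringsAsFactors = FALSE)
}

#' Genomic relationship matrix from marker allele counts
#'
#' Genome-wide average of single-marker statistics:
#' `G[i,j] = (1/m) * sum_k (x[i,k] - 2 p_k)(x[j,k] - 2 p_k) / (2 p_k (1 - p_k))`.
#' By default the diagonal uses the same cross-product form, which keeps `G`
#' positive semi-definite; `diag = "yang"` applies the within-individual
#' correction `1 + (1/m) sum_k (x^2 - (1 + 2p) x + 2 p^2) / (2 p q)` instead.
#'
#' @param X allele-count matrix, individuals x markers, values 0/1/2, with
#'   individual ids as row names.
#' @param p per-marker frequencies of the counted allele; computed from `X`
#'   when NULL, in which case monomorphic markers are dropped. Supplied
#'   frequencies must lie strictly inside (0, 1).
#' @param diag_method `"crossproduct"` (default) or `"yang"`.
#' @return symmetric matrix with the row names of `X` as dimnames.
#' @export
genomic_G <- function(X, p = NULL,
                      diag_method = c("crossproduct", "yang")) {
  diag_method <- match.arg(diag_method)
  X <- as.matrix(X)
  if (is.null(p)) {
    p <- colMeans(X) / 2
    keep <- p > 0 & p < 1
    X <- X[, keep, drop = FALSE]
    p <- p[keep]
  } else {
    if (length(p) != ncol(X))
      stop("'p' must have one frequency per marker")
    if (any(p <= 0 | p >= 1))
      stop("marker frequencies at 0 or 1 must be filtered out")
  }
  m <- ncol(X)
  if (m == 0L) stop("no polymorphic markers left")
  W <- sweep(X, 2L, 2 * p)
  W <- sweep(W, 2L, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(W) / m
  if (diag_method == "yang") {
    d <- numeric(nrow(X))
    for (k in seq_len(m)) {
      x <- X[, k]
      d <- d + (x^2 - (1 + 2 * p[k]) * x + 2 * p[k]^2) /
        (2 * p[k] * (1 - p[k]))
    }
    diag(G) <- 1 + d / m
  }
  G
}

#' Coancestry block between selected sires and dams
#'
#' Element `[i, j]` is the expected coancestry `f = relationship / 2` of sire
#' `i` and dam `j`, which equals the inbreeding coefficient of their
#' prospective offspring.
#'
#' @param relmat relationship matrix (pedigree `A` or genomic `G`) with id
#'   dimnames.
#' @param sire_ids,dam_ids ids present in `relmat`.
#' @return `length(sire_ids)` x `length(dam_ids)` matrix.
#' @export
coancestry_block <- function(relmat, sire_ids, dam_ids) {
  ids <- rownames(relmat)
  s <- match(as.character(sire_ids), ids)
  d <- match(as.character(dam_ids), ids)
  if (anyNA(s) || anyNA(d))
    stop("sire or dam id not present in the relationship matrix")
  0.5 * relmat[s, d, drop = FALSE]
}

#' Normed lower-triangular ancestral-contribution matrix L
#'
#' `L[i, a]` is the expected genetic contribution of ancestor `a` to
#' individual `i` (`L[i, i] = 1`). For a pedigree, L is built by the
#' recursion `L[i, a] = (L[sire, a] + L[dam, a]) / 2`. For a relationship
#' matrix ordered oldest to youngest, L is the unit-triangular factor of its
#' LDL' decomposition (Cholesky with escalating diagonal jitter from `1e-8`
#' to `1e-4` if needed, each column of the raw factor divided by its
#' diagonal entry so that `diag(L) = 1`). Applied to a pedigree `A`, the
#' decomposition route reproduces the recursion exactly.
#'
#' @param x a pedigree data frame (`id`, `sire`, `dam`, parents first) or a
#'   symmetric relationship matrix ordered oldest to youngest with id
#'   dimnames.
#' @return lower-triangular matrix, rows = individuals, columns = ancestors.
#' @export
contribution_L <- function(x) {
  if (is.data.frame(x)) {
    ped <- normalize_pedigree(x)
    n <- nrow(ped)
    L <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
    for (i in seq_len(n)) {
      s <- ped$si[i]; d <- ped$di[i]
      if (i > 1L) {
        j <- seq_len(i - 1L)
        row <- numeric(i - 1L)
        if (!is.na(s)) row <- row + L[s, j]
        if (!is.na(d)) row <- row + L[d, j]
        L[i, j] <- row / 2
      }
      L[i, i] <- 1
    }
    return(L)
  }
  K <- as.matrix(x)
  if (nrow(K) != ncol(K)) stop("relationship matrix must be square")
  n <- nrow(K)
  R <- NULL
  for (jit in c(0, 1e-8, 1e-6, 1e-4)) {
    R <- tryCatch(chol(K + diag(jit, n)), error = function(e) NULL)
    if (!is.null(R)) break
  }
  if (is.null(R))
    stop("relationship matrix could not be factorized even with jitter")
  L0 <- t(R)
  L <- sweep(L0, 2L, diag(L0), "/")
  dimnames(L) <- dimnames(K)
  L
}

#' Genetic contributions of ancestors to allocated matings
#'
#' Column `m` of `C` holds, for every ancestor `a`, the expected contribution
#' to mating `m`: `C[a, m] = (L[sire(m), a] + L[dam(m), a]) / 2`. Current
#' parents contribute one half to their own matings (`L[i, i] = 1`).
#'
#' @param L contribution matrix (rows = individuals incl. all plan parents,
#'   columns = ancestors).
#' @param sires,dams parent ids per mating (equal length).
#' @return matrix, ancestors x matings.
#' @export
contributions_to_matings <- function(L, sires, dams) {
  ids <- rownames(L)
  s <- match(as.character(sires), ids)
  d <- match(as.character(dams), ids)
  if (anyNA(s) || anyNA(d))
    stop("mating plan parent absent from the contribution matrix")
  0.5 * t(L[s, , drop = FALSE] + L[d, , drop = FALSE])
}

#' Long-term genetic contributions of ancestors to a target cohort
#'
#' The mean, over the individuals of a (distant) descendant cohort, of each
#' ancestor's contribution — the expected fraction of the cohort's genome
#' deriving from that ancestor.
#'
#' @param L contribution matrix (rows = individuals, columns = ancestors).
#' @param target_ids ids of the target-cohort rows of `L`.
#' @return named numeric vector, one value per ancestor column of `L`.
#' @export
long_term_contributions <- function(L, target_ids) {
  r <- match(as.character(target_ids), rownames(L))
  if (length(r) == 0L) stop("target cohort is empty")
  if (anyNA(r)) stop("target id absent from the contribution matrix")
  colMeans(L[r, , drop = FALSE])
}

#' Read / write pedigrees as 4-column tab-separated text
#'
#' Columns `id`, `sire`, `dam`, `generation`; 0 denotes an unknown parent.
#'
#' @param path file path.
#' @rdname pedigree_io
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ped
}

#' @param ped pedigree data frame.
#' @rdname pedigree_io
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a relationship or contribution matrix as tab-separated text
#'
#' Dense export with a header row of ids and the row id as first column.
#'
#' @param m matrix with id dimnames.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_relmatrix <- function(m, path) {
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
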