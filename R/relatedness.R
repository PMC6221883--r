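#' Discrete sib-class relatedness coefficient
#'
#' The convention used when relatedness is read directly off parentage
#' classes: 0.25 for half sibs (exactly one shared parent), 0.5 for full
#' sibs (both parents shared, dam != sire), 1.0 for larvae produced by
#' selfing of the same colony (dam = sire = same parent, sharing all
#' genetic material like clones), 0 otherwise; an individual paired with
#' itself is 1.0.
#'
#' @param ped a `pedigree`.
#' @param a,b individual ids present in the pedigree.
#' @return a single coefficient in `{0, 0.25, 0.5, 1}`.
#' @export
relatedness_sibclass <- function(ped, a, b) {
  idx <- match(c(a, b), ped$individual)
  if (anyNA(idx))
    stop("individual(s) not in pedigree: ",
         paste(c(a, b)[is.na(idx)], collapse = ", "))
  if (a == b) return(1.0)
  pa <- c(ped$dam[idx[1L]], ped$sire[idx[1L]])
  pb <- c(ped$dam[idx[2L]], ped$sire[idx[2L]])
  if (anyNA(pa) || anyNA(pb)) {            # founders: unrelated under this convention
    shared <- length(intersect(pa[!is.na(pa)], pb[!is.na(pb)]))
    return(if (shared >= 1L) 0.25 else 0.0)
  }
  selfed_a <- pa[1L] == pa[2L]
  selfed_b <- pb[1L] == pb[2L]
  if (selfed_a && selfed_b && pa[1L] == pb[1L]) return(1.0)
  if (setequal(pa, pb) && pa[1L] != pa[2L]) return(0.5)
  if (length(intersect(unique(pa), unique(pb))) >= 1L) return(0.25)
  0.0
}

#' Relatedness matrix under the discrete sib-class convention
#'
#' Applies [relatedness_sibclass()] to every pair of the requested
#' individuals. The resulting matrix (unit diagonal, off-diagonals in
#' `{0, 0.25, 0.5, 1}`) is not guaranteed positive semi-definite; when it
#' is not, it is projected to the nearest PSD matrix by eigenvalue
#' clipping (at 1e-10) so it can serve as a covariance structure.
#'
#' @param ped a `pedigree`.
#' @param ids individuals to include (default: all non-founders).
#' @param project_psd clip negative eigenvalues (default TRUE).
#' @return matrix of class `relatedness_matrix` with attribute
#'   `convention = "sibclass"`.
#' @export
relatedness_matrix_sibclass <- function(ped, ids = NULL, project_psd = TRUE) {
  if (is.null(ids))
    ids <- ped$individual[!is.na(ped$dam) | !is.na(ped$sire)]
  idx <- match(ids, ped$individual)
  if (anyNA(idx))
    stop("individual(s) not in pedigree: ",
         paste(ids[is.na(idx)], collapse = ", "))
  da <- ped$dam[idx]; si <- ped$sire[idx]
  n <- length(ids)
  eq <- function(a, b) {             # outer equality, NA compares FALSE
    m <- outer(a, b, "==")
    m[is.na(m)] <- FALSE
    m
  }
  dd <- eq(da, da); ss <- eq(si, si); ds <- eq(da, si)
  any_share <- dd | ss | ds | t(ds)
  full <- (dd & ss) | (ds & t(ds))   # parent sets coincide
  selfed <- !is.na(da) & !is.na(si) & da == si
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[any_share] <- 0.25
  A[full] <- 0.5
  A[full & outer(selfed, selfed, "&")] <- 1.0
  diag(A) <- 1
  if (project_psd) A <- nearest_psd(A)
  structure(A, convention = "sibclass", class = c("relatedness_matrix", "matrix", "array"))
}

#' Additive relationship matrix by the recursive tabular method
#'
#' The numerator relationship matrix A over the whole (sorted) pedigree:
#' founders have `a_ii = 1`, `a_ij = 0`; for offspring j with parents s, d,
#' `a_ij = (a_is + a_id) / 2` for earlier i, and
#' `a_jj = 1 + a_sd / 2` (the inbreeding increment). Unknown parents
#' contribute 0. PSD by construction.
#'
#' @param ped a `pedigree` (already topologically sorted).
#' @param ids optional subset of individuals for the returned matrix (the
#'   recursion always runs over the full pedigree).
#' @return matrix of class `relatedness_matrix`, attribute
#'   `convention = "tabular"`; diagonal `>= 1`.
#' @export
relatedness_tabular <- function(ped, ids = NULL) {
  n <- nrow(ped)
  id <- ped$individual
  di <- match(ped$dam, id)   # NA for unknown
  si <- match(ped$sire, id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (j in seq_len(n)) {
    d <- di[j]; s <- si[j]
    if (is.na(d) && is.na(s)) {
      A[j, j] <- 1
    } else {
      for (i in seq_len(j - 1L)) {
        aid <- if (is.na(d)) 0 else A[i, d]
        ais <- if (is.na(s)) 0 else A[i, s]
        A[i, j] <- A[j, i] <- (aid + ais) / 2
      }
      asd <- if (is.na(d) || is.na(s)) 0 else A[s, d]
      A[j, j] <- 1 + asd / 2
    }
  }
  if (!is.null(ids)) {
    miss <- setdiff(ids, id)
    if (length(miss)) stop("not in pedigree: ", paste(miss, collapse = ", "))
    A <- A[ids, ids, drop = FALSE]
  }
  structure(A, convention = "tabular", class = c("relatedness_matrix", "matrix", "array"))
}

#' Nearest positive semi-definite projection
#'
#' Symmetrizes, clips eigenvalues below `eps`, and reconstructs. Used for
#' the discrete-coefficient relatedness matrix, which is not PSD by
#' construction.
#'
#' @param A square symmetric-ish matrix.
#' @param eps eigenvalue floor.
#' @return PSD matrix with the same dimnames.
#' @export
nearest_psd <- function(A, eps = 1e-10) {
  A <- (A + t(A)) / 2
  # positive definite matrices need no projection; chol is the cheap test
  if (!inherits(try(chol(A), silent = TRUE), "try-error")) return(A)
  e <- eigen(A, symmetric = TRUE)
  if (all(e$values >= eps)) return(A)
  B <- e$vectors %*% (pmax(e$values, eps) * t(e$vectors))
  dimnames(B) <- dimnames(A)
  (B + t(B)) / 2
}
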