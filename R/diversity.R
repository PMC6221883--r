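#' Pairwise p-distance between two sequences
#'
#' Fraction of compared sites that differ under the raw (uncorrected) model
#' of molecular evolution. Sites with `N` or `-` in either sequence are
#' excluded from both numerator and denominator. Sequences of unequal
#' length are compared over their leading overlap, which must cover at
#' least `min_overlap` of the longer sequence; no alignment is attempted.
#'
#' @param seq_a,seq_b nucleotide strings.
#' @param min_overlap minimum overlap fraction of the longer sequence.
#' @return distance in `[0, 1]`.
#' @export
p_distance <- function(seq_a, seq_b, min_overlap = 0.8) {
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  len <- min(length(a), length(b))
  if (len < min_overlap * max(length(a), length(b)))
    stop("sequence overlap ", len, " below the minimum fraction ", min_overlap,
         " of the longer sequence (", max(length(a), length(b)), " bp); ",
         "supply pre-aligned sequences")
  a <- a[seq_len(len)]; b <- b[seq_len(len)]
  ok <- !(a %in% c("N", "-")) & !(b %in% c("N", "-"))
  if (!any(ok)) stop("no comparable sites between the two sequences")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Sequence-similarity matrix over a set of OTU representatives
#'
#' `Z[i, j] = 1 - d(i, j)` with `d` the raw pairwise p-distance (pairwise
#' deletion of `N`/gap sites, as in `ape::dist.dna(model = "raw",
#' pairwise.deletion = TRUE)`); the diagonal is exactly 1.
#'
#' @param seqs a `sequence_set` of at least two equal-length (or
#'   sufficiently overlapping) sequences.
#' @return symmetric matrix with entries in `[0, 1]`, unit diagonal,
#'   dimnames = OTU ids.
#' @export
similarity_matrix <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) == 1L) {
    bin <- ape::as.DNAbin(lapply(strsplit(tolower(unclass(seqs)), ""), identity))
    names(bin) <- names(seqs)
    d <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
    if (anyNA(d)) {
      bad <- which(is.na(d), arr.ind = TRUE)[1L, ]
      stop("no comparable sites between '", names(seqs)[bad[1L]], "' and '",
           names(seqs)[bad[2L]], "'")
    }
  } else {
    d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      dij <- tryCatch(p_distance(seqs[[i]], seqs[[j]]), error = function(e)
        stop("pair (", names(seqs)[i], ", ", names(seqs)[j], "): ",
             conditionMessage(e), call. = FALSE))
      d[i, j] <- d[j, i] <- dij
    }
  }
  z <- 1 - d
  diag(z) <- 1
  dimnames(z) <- list(names(seqs), names(seqs))
  z
}

#' Similarity-sensitive diversity of order q
#'
#' The Leinster-Cobbold effective number of a relative-abundance vector `p`
#' under a similarity matrix `Z`. Writing `(Zp)_i = sum_j Z_ij p_j`, the
#' ordinariness of species i, the diversity is
#' \deqn{{}^{q}D^{Z}(p) = \Big(\sum_{i: p_i > 0} p_i (Zp)_i^{q-1}\Big)^{1/(1-q)}}
#' for `q != 1`, the limit \eqn{\prod_i (Zp)_i^{-p_i}} at `q = 1`, and
#' \eqn{1 / \max_i (Zp)_i} at `q = Inf` (maxima over the support of p).
#' `Z = I` recovers the classical Hill numbers; `Z = 1` (all species
#' identical) collapses every community to diversity 1.
#'
#' @param p non-negative abundance vector; renormalized internally to sum 1.
#' @param Z similarity matrix conformable with `p` (entries in `[0, 1]`,
#'   unit diagonal).
#' @param q order of the diversity, `>= 0`; `Inf` allowed.
#' @return a single effective-number value, `1 <= D <= richness(p)`.
#' @export
leinster_cobbold <- function(p, Z, q) {
  if (q < 0) stop("q must be non-negative")
  if (any(p < 0)) stop("abundances must be non-negative")
  tot <- sum(p)
  if (tot <= 0) stop("abundance vector sums to zero")
  p <- p / tot
  if (length(p) != nrow(Z)) stop("p and Z dimensions do not match")
  sup <- p > 0
  zp <- drop(Z %*% p)[sup]   # ordinariness over the support
  ps <- p[sup]
  if (is.infinite(q)) return(1 / max(zp))
  if (abs(q - 1) < 1e-9) return(prod(zp ^ (-ps)))
  sum(ps * zp ^ (q - 1)) ^ (1 / (1 - q))
}

#' Per-sample diversity profiles from an OTU table
#'
#' Converts median-of-ratios-normalized counts to relative abundances and
#' evaluates the similarity-sensitive diversity at each order in `q_grid`.
#' The value at `trait_q` is flagged as the scalar host trait used for
#' heritability analysis.
#'
#' @param table an `otu_table`.
#' @param s size factors from [size_factors()] (or `NULL` to skip depth
#'   normalization; proportions are depth-invariant, normalization matters
#'   for the variance stabilization convention).
#' @param Z similarity matrix over the table's OTUs.
#' @param q_grid numeric vector of orders; may include `Inf`.
#' @param trait_q which order is the exported trait (must be in `q_grid`).
#' @return a data.frame of class `diversity_profile` with columns
#'   `sample_id`, `q`, `D`, `is_trait`. All-zero samples yield `NA` with a
#'   warning.
#' @export
diversity_profile <- function(table, s = NULL, Z, q_grid = c(0, 1, 2, Inf),
                              trait_q = 1) {
  stopifnot(inherits(table, "otu_table"))
  if (!trait_q %in% q_grid) q_grid <- sort(c(q_grid, trait_q))
  if (!all(table$otu_ids %in% rownames(Z)))
    stop("similarity matrix lacks OTU(s): ",
         paste(utils::head(setdiff(table$otu_ids, rownames(Z))), collapse = ", "))
  Z <- Z[table$otu_ids, table$otu_ids]
  x <- normalize_counts(table, s)
  rows <- vector("list", nrow(x))
  for (j in seq_len(nrow(x))) {
    p <- x[j, ]
    if (sum(p) <= 0) {
      warning("sample '", rownames(x)[j], "' has zero total count; trait is NA")
      D <- rep(NA_real_, length(q_grid))
    } else {
      D <- vapply(q_grid, function(q) leinster_cobbold(p, Z, q), numeric(1))
    }
    rows[[j]] <- data.frame(sample_id = rownames(x)[j], q = q_grid, D = D,
                            is_trait = q_grid == trait_q)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diversity_profile", "data.frame")
  out
}

#' Extract the scalar diversity trait from a profile
#'
#' @param profile a `diversity_profile`.
#' @return named numeric vector: sample_id -> trait value (the profile at
#'   the trait order).
#' @export
diversity_trait <- function(profile) {
  tr <- profile[profile$is_trait, ]
  stats::setNames(tr$D, tr$sample_id)
}
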