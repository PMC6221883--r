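#' Median-of-ratios size factors
#'
#' Corrects for variable sequencing depth across samples. With counts
#' `k[j, i]` (sample j, OTU i) and `g_i` the geometric mean of OTU i across
#' samples, `s_j = median_i(k[j, i] / g_i)` over the reference set of OTUs
#' with `g_i > 0` (i.e. OTUs observed in every sample). For sparse tables
#' where no OTU is ubiquitous, `pseudo_reference = TRUE` computes each
#' `g_i` over the positive counts only.
#'
#' @param table an `otu_table` or a counts matrix (samples x OTUs).
#' @param pseudo_reference fall back to positive-count geometric means.
#' @return positive numeric vector of per-sample size factors, named by
#'   sample.
#' @export
size_factors <- function(table, pseudo_reference = FALSE) {
  k <- if (inherits(table, "otu_table")) table$counts else table
  logk <- log(k)
  if (pseudo_reference) {
    logg <- apply(logk, 2L, function(v) mean(v[is.finite(v)]))
  } else {
    logg <- colMeans(logk)            # -Inf wherever any sample has a zero
  }
  use <- is.finite(logg)
  if (!any(use))
    stop("no OTU is present in all samples, so the reference set is empty; ",
         "re-run with pseudo_reference = TRUE")
  s <- apply(logk[, use, drop = FALSE], 1L, function(row) {
    r <- row - logg[use]
    exp(stats::median(r[is.finite(r)]))
  })
  if (any(!is.finite(s) | s <= 0))
    stop("degenerate size factor for sample(s): ",
         paste(rownames(k)[!is.finite(s) | s <= 0], collapse = ", "))
  s
}

#' Depth-normalize a count table
#'
#' Divides each sample's counts by its size factor; `normalize_counts(t, s)[j, i]
#' = k[j, i] / s[j]`.
#'
#' @param table an `otu_table` or counts matrix.
#' @param s size factors from [size_factors()]; `NULL` means all 1.
#' @return real-valued matrix of normalized counts.
#' @export
normalize_counts <- function(table, s = NULL) {
  k <- if (inherits(table, "otu_table")) table$counts else table
  if (is.null(s)) return(k + 0)
  if (length(s) != nrow(k))
    stop("size factors (", length(s), ") do not match samples (", nrow(k), ")")
  if (!is.null(names(s)) && !is.null(rownames(k))) s <- s[rownames(k)]
  sweep(k, 1L, s, "/")
}

#' Negative-binomial Wald test of differential OTU abundance
#'
#' Per OTU, fits the mean model `mu[j] = s[j] * exp(b0 + b1 * group[j])` on
#' raw counts with a per-OTU negative-binomial dispersion estimated by
#' method of moments on normalized counts (floored at 1e-8; no shrinkage
#' across OTUs and no independent filtering, a deliberate simplification
#' relative to the large empirical-Bayes machinery of tools like DESeq2).
#' The Wald statistic is `b1 / SE(b1)`; `log2fc = b1 / ln 2`. OTUs with all
#' zero counts get `NA` p-values and are excluded from the BH family.
#'
#' @param table an `otu_table` or counts matrix (samples x OTUs).
#' @param group_labels two-level factor/character vector over samples. The
#'   first level (alphabetical, or factor level order) is the reference;
#'   positive `log2fc` means more abundant in the second level.
#' @param s size factors (default: computed from the table, with automatic
#'   pseudo-reference fallback).
#' @param alpha BH significance level.
#' @return data.frame of class `da_result`: `otu_id`, `baseMean` (mean of
#'   normalized counts), `log2fc`, `wald_z`, `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
nb_wald_test <- function(table, group_labels, s = NULL, alpha = 0.05) {
  k <- if (inherits(table, "otu_table")) table$counts else table
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stop("exactly two groups required, got ", nlevels(g))
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
  if (length(g) != nrow(k)) stop("group labels do not match samples")
  if (is.null(s)) {
    s <- tryCatch(size_factors(k),
                  error = function(e) size_factors(k, pseudo_reference = TRUE))
  }
  norm <- normalize_counts(k, s)
  res <- data.frame(otu_id = colnames(k), baseMean = colMeans(norm),
                    log2fc = NA_real_, wald_z = NA_real_, p_value = NA_real_)
  for (i in seq_len(ncol(k))) {
    y <- k[, i]
    if (all(y == 0)) next
    # method-of-moments dispersion on normalized counts: var = mu + a mu^2
    xn <- norm[, i]
    mu <- mean(xn)
    a <- max((stats::var(xn) - mu) / mu^2, 1e-8)
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ g + offset(log(s)),
                                  family = MASS::negative.binomial(theta = 1 / a))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sm <- suppressWarnings(summary(fit)$coefficients)
    if (nrow(sm) < 2L || !is.finite(sm[2L, 2L]) || sm[2L, 2L] <= 0) next
    b1 <- sm[2L, 1L]; se <- sm[2L, 2L]
    res$log2fc[i] <- b1 / log(2)
    res$wald_z[i] <- b1 / se
    res$p_value[i] <- 2 * stats::pnorm(-abs(b1 / se))
  }
  adj <- bh_adjust(res$p_value, alpha = alpha)
  res$p_adjusted <- adj$p_adjusted
  res$significant <- adj$reject
  class(res) <- c("da_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR control: sort p ascending, `adj_(i) = min_{j >= i}
#' p_(j) * m / j` capped at 1, with `m` the number of non-missing p-values
#' (NAs are excluded from the family and propagate as NA).
#'
#' @param p p-values in `[0, 1]`, NA allowed.
#' @param alpha rejection level for the `reject` flags.
#' @return list with `p_adjusted` and logical `reject`.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Fold multiplier from a log2 fold change
#'
#' @param log2fc finite real log2 fold change(s).
#' @param digits rounding for display (default 1 decimal place, the
#'   convention used when reporting e.g. `2.5 log2 fold = 5.7 times`).
#' @return `2^log2fc`, rounded.
#' @export
fold_from_log2 <- function(log2fc, digits = 1) {
  stopifnot(all(is.finite(log2fc)))
  round(2 ^ log2fc, digits)
}
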