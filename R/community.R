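#' Bray-Curtis dissimilarity matrix
#'
#' `d_jk = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)` over (typically
#' depth-normalized) abundances; computed with `vegan::vegdist`.
#'
#' @param x non-negative matrix, rows = samples; no all-zero rows.
#' @return symmetric matrix with zero diagonal, entries in `[0, 1]`.
#' @export
bray_curtis <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  zero <- rowSums(x) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(rownames(x)[zero], collapse = ", "))
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' Principal coordinates analysis
#'
#' Eigen-decomposition of the Gower double-centered matrix `-D^2/2`.
#' Negative eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are retained and reported, with coordinates for both the
#' real (positive-eigenvalue) and imaginary (negative-eigenvalue) axes;
#' no Cailliez/Lingoes correction is applied.
#'
#' @param D symmetric dissimilarity matrix, zero diagonal.
#' @return list: `points` (samples x positive axes, scaled so squared
#'   distances reproduce Euclidean parts), `imaginary_points`,
#'   `eigenvalues` (all, descending).
#' @export
pcoa <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  G <- -0.5 * D^2
  G <- sweep(G, 1L, rowMeans(G))
  G <- sweep(G, 2L, colMeans(G))   # Gower centering (grand mean restored)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  neg <- e$values < -tol
  pts <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  ipts <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), sum(neg))
  rownames(pts) <- rownames(ipts) <- rownames(D)
  list(points = pts, imaginary_points = ipts, eigenvalues = e$values)
}

#' Permutational multivariate analysis of variance
#'
#' One-way PERMANOVA on a dissimilarity matrix: pseudo-F from the
#' sums-of-squares decomposition `SS_total = (1/n) sum_{j<k} d_jk^2`,
#' `SS_within = sum_g (1/n_g) sum_{j<k in g} d_jk^2`, with the p-value from
#' free permutation of sample labels under the `(1 + #{F* >= F}) /
#' (1 + n_perm)` convention. Delegates to `vegan::adonis2`.
#'
#' @param D dissimilarity matrix (class `dist` or square matrix).
#' @param labels grouping vector (>= 2 groups).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list of class `permanova_result`: `f`, `r2`, `df_between`,
#'   `df_within`, `p`, `n_perm`.
#' @export
permanova <- function(D, labels, n_perm = 999, seed = 1L) {
  d <- stats::as.dist(D)
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("need at least two groups")
  set.seed(as.integer(seed))
  df <- data.frame(g = g)
  fit <- vegan::adonis2(d ~ g, data = df, permutations = n_perm)
  structure(list(f = fit$F[1L], r2 = fit$R2[1L],
                 df_between = fit$Df[1L], df_within = fit$Df[2L],
                 p = fit$`Pr(>F)`[1L], n_perm = n_perm),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, df = (%d, %d), p = %.4g (%d permutations)\n",
              x$f, x$r2, x$df_between, x$df_within, x$p, x$n_perm))
  invisible(x)
}

#' Homogeneity of multivariate dispersions
#'
#' Distances of samples to their group centroid in PCoA space (negative
#' eigenvalue axes subtract from the squared distance, floored at zero),
#' followed by a one-way F test with a permutation p-value; delegates to
#' `vegan::betadisper` + `vegan::permutest`. Groups of size 1 are excluded
#' with a warning. If all within-group distances are zero the F statistic
#' is undefined and `NA` is returned with a warning.
#'
#' @param D dissimilarity matrix.
#' @param labels grouping vector.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return list: `f`, `p`, `df`, `distances` (per retained sample).
#' @export
betadisper_test <- function(D, labels, n_perm = 999, seed = 1L) {
  g <- factor(labels)
  keep <- g %in% names(which(table(g) >= 2L))
  if (!all(keep)) {
    warning("excluding ", sum(!keep), " sample(s) in singleton group(s)")
    D <- as.matrix(D)[keep, keep]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2L) stop("need at least two groups of size >= 2")
  bd <- vegan::betadisper(stats::as.dist(as.matrix(D)), g)
  if (all(bd$distances < 1e-12)) {
    warning("all distances to centroids are zero; dispersion F undefined")
    return(list(f = NA_real_, p = NA_real_, df = nlevels(g) - 1L,
                distances = bd$distances))
  }
  set.seed(as.integer(seed))
  pt <- vegan::permutest(bd, permutations = n_perm)
  list(f = pt$tab$F[1L], p = pt$tab$`Pr(>F)`[1L],
       df = pt$tab$Df[1L], distances = bd$distances)
}

#' Shared / stage-specific OTU partition
#'
#' Classifies each OTU as present in adults, larvae, or both, using total
#' raw stage counts above `threshold` (default: present means any read).
#'
#' @param table an `otu_table`.
#' @param threshold minimum total stage count to call presence (default 0,
#'   i.e. `> 0`).
#' @return list: `shared`, `adult_only`, `larva_only` (character vectors of
#'   OTU ids) and `counts` (named numeric of the three set sizes).
#' @export
shared_unique_partition <- function(table, threshold = 0) {
  stopifnot(inherits(table, "otu_table"))
  stage <- table$metadata$life_stage
  if (!all(c("adult", "larva") %in% stage)) stop("both life stages required")
  tot_a <- colSums(table$counts[stage == "adult", , drop = FALSE])
  tot_l <- colSums(table$counts[stage == "larva", , drop = FALSE])
  in_a <- tot_a > threshold; in_l <- tot_l > threshold
  out <- list(shared = table$otu_ids[in_a & in_l],
              adult_only = table$otu_ids[in_a & !in_l],
              larva_only = table$otu_ids[!in_a & in_l])
  out$counts <- c(shared = length(out$shared),
                  adult_only = length(out$adult_only),
                  larva_only = length(out$larva_only))
  out
}

#' Brood-OTU prevalence network
#'
#' Bipartite brood x OTU edges: per brood (larvae sharing a dam), an OTU's
#' prevalence is the fraction of larvae carrying it (raw count > 0); edges
#' are retained at `prevalence >= threshold`, weighted by the mean relative
#' abundance in the brood. OTUs ubiquitous at 100% prevalence in every
#' brood are flagged `core` (the convention under which such edges are
#' dropped from network figures).
#'
#' @param table an `otu_table` (the larval rows are used).
#' @param threshold prevalence cut in (0, 1], default 0.5.
#' @return data.frame of class `prevalence_network`: `brood`, `otu_id`,
#'   `prevalence`, `mean_rel_abundance`, `core`.
#' @export
prevalence_network <- function(table, threshold = 0.5) {
  stopifnot(inherits(table, "otu_table"))
  larv <- table$metadata$life_stage == "larva"
  if (!any(larv)) stop("no larvae in table")
  k <- table$counts[larv, , drop = FALSE]
  dams <- table$metadata$dam_id[larv]
  broods <- split(seq_len(nrow(k)), dams)
  empty <- names(broods)[lengths(broods) == 0L]
  if (length(empty)) warning("excluding empty brood(s): ",
                             paste(empty, collapse = ", "))
  broods <- broods[lengths(broods) > 0L]
  rel <- k / rowSums(k)
  prev <- t(vapply(broods, function(idx)
    colMeans(k[idx, , drop = FALSE] > 0), numeric(ncol(k))))
  core_otu <- colnames(k)[apply(prev == 1, 2L, all)]
  rows <- lapply(names(broods), function(b) {
    idx <- broods[[b]]
    keep <- which(prev[b, ] >= threshold)
    if (!length(keep)) return(NULL)
    data.frame(brood = b, otu_id = colnames(k)[keep],
               prevalence = prev[b, keep],
               mean_rel_abundance = colMeans(rel[idx, keep, drop = FALSE]),
               core = colnames(k)[keep] %in% core_otu,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("prevalence_network", "data.frame")
  out
}

#' Pairwise Spearman rank correlations among OTUs
#'
#' Average-rank ties; two-sided p-values from the t approximation
#' (`cor.test(..., method = "spearman", exact = FALSE)`). Constant vectors
#' yield NA with a warning.
#'
#' @param x matrix of (normalized) abundances, rows = samples (>= 3),
#'   columns = the selected OTUs.
#' @return list of matrices `rho` and `p` (diagonal NA).
#' @export
spearman_pairs <- function(x) {
  if (nrow(x) < 3L) stop("need at least 3 samples")
  m <- ncol(x)
  rho <- p <- matrix(NA_real_, m, m, dimnames = list(colnames(x), colnames(x)))
  const <- apply(x, 2L, function(v) stats::var(v) == 0)
  if (any(const)) warning("constant OTU vector(s): ",
                          paste(colnames(x)[const], collapse = ", "))
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (const[i] || const[j]) next
    ct <- suppressWarnings(stats::cor.test(x[, i], x[, j], method = "spearman",
                                           exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(rho = rho, p = p)
}

#' Spatial linear model of OTU abundance
#'
#' Ordinary least squares of the square-root-transformed abundance on
#' centered coordinates and their interaction:
#' `sqrt(abundance) ~ xc + yc + xc:yc`. Square-root transformation
#' stabilizes count-like abundances; centering makes the intercept the
#' fitted response at the plot centroid.
#'
#' @param abundance non-negative vector over samples.
#' @param x,y coordinates in metres (>= 6 samples, not collinear).
#' @return list: `coefficients` (term, estimate, se, t, p data.frame) and
#'   `fit` (the `lm` object).
#' @export
spatial_linear_model <- function(abundance, x, y) {
  if (length(abundance) < 6L) stop("need at least 6 samples with coordinates")
  if (any(abundance < 0)) stop("abundance must be non-negative")
  xc <- x - mean(x); yc <- y - mean(y)
  if (stats::var(xc) == 0 || stats::var(yc) == 0 ||
      abs(stats::cor(xc, yc)) > 1 - 1e-10)
    stop("coordinates are collinear or constant")
  fit <- stats::lm(sqrt(abundance) ~ xc + yc + xc:yc)
  sm <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(sm), estimate = sm[, 1L],
                                 se = sm[, 2L], t = sm[, 3L], p = sm[, 4L],
                                 row.names = NULL),
       fit = fit)
}

#' Differential abundance among adult size classes
#'
#' All-pairs negative-binomial Wald tests between size classes (delegating
#' to [nb_wald_test()]) with a single pooled BH family across every pair
#' and OTU. Singleton classes are excluded with a warning.
#'
#' @param table an `otu_table` (adult rows are used).
#' @param alpha BH level.
#' @return data.frame: `class_a`, `class_b` plus the [nb_wald_test()]
#'   columns, with `p_adjusted`/`significant` recomputed over the pooled
#'   family.
#' @export
sizeclass_da <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "otu_table"))
  ad <- table$metadata$life_stage == "adult"
  k <- table$counts[ad, , drop = FALSE]
  cls <- table$metadata$size_class[ad]
  tab <- table(cls)
  singles <- names(tab)[tab < 2L]
  if (length(singles))
    warning("excluding singleton size class(es): ",
            paste(singles, collapse = ", "))
  keep_cls <- names(tab)[tab >= 2L]
  if (length(keep_cls) < 2L) stop("need >= 2 size classes with >= 2 samples")
  pairs <- utils::combn(sort(keep_cls), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    sel <- cls %in% c(a, b)
    r <- nb_wald_test(k[sel, , drop = FALSE], cls[sel], alpha = alpha)
    data.frame(class_a = a, class_b = b, as.data.frame(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  adj <- bh_adjust(out$p_value, alpha = alpha)
  out$p_adjusted <- adj$p_adjusted
  out$significant <- adj$reject
  rownames(out) <- NULL
  out
}
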