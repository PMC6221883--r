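#' Configuration for the synthetic mating-design simulator
#'
#' Defaults mirror the statistical structure of the study system: 9 dams,
#' 45 candidate sires (including the dams, which can self), 60 brooded
#' larvae of which 4 are selfed, 161 OTUs of which 93 occur only in larvae
#' and 17 only in adults, dominant C-clade types plus background A/D types,
#' spatially heterogeneous adult communities over a 16 m x 40 m plot, and
#' mixed-mode symbiont transmission with vertical fidelity `v`.
#'
#' `v` is the mixture weight of the maternal community in each larva's
#' expected composition (the remainder comes from a shared environmental
#' pool that includes the larva-only types). The study does not quantify
#' this ratio; 0.9 encodes predominantly vertical transmission with a
#' horizontal complement.
#'
#' Heritability is injected through the community-evenness channel: each
#' larva's Dirichlet concentration is `exp(gamma0 + a_l + e_l)` with
#' breeding values `a ~ N(0, sigma2_a A)` from the pedigree, so the scalar
#' diversity trait is heritable with latent-scale
#' `h2 = sigma2_a / (sigma2_a + sigma2_e (+ sigma2_m))`.
#'
#' @param n_dams,n_sires,n_larvae,n_selfed mating design counts; the sire
#'   pool contains the dams, `n_sires >= n_dams`.
#' @param n_otus,n_larval_specific_otus,n_adult_specific_otus OTU pool
#'   partition.
#' @param n_clades number of sequence clusters (clades) for the simulated
#'   representatives.
#' @param seq_len representative sequence length (bp).
#' @param read_depth_mean,read_depth_dispersion lognormal library-size
#'   model: `depth ~ lognormal(log(read_depth_mean), read_depth_dispersion)`.
#' @param v vertical fidelity in `[0, 1]`.
#' @param winnowing_exponent sharpening of the maternal contribution:
#'   maternal proportions are raised to this power (and renormalized)
#'   before mixing, so dominant types are transmitted preferentially while
#'   the adult background tail is winnowed out. 1 = proportional
#'   transmission; the default 2 encodes the ontogenetic winnowing regime
#'   in which larval communities are dominated by the dam's main symbionts
#'   yet remain distinct from whole adult communities.
#' @param env_pool_concentration Dirichlet concentration of the shared
#'   environmental pool.
#' @param gamma0 baseline log concentration of the larval Dirichlet draw.
#' @param sigma2_a,sigma2_e,sigma2_m latent additive, residual and maternal
#'   variances of the evenness channel.
#' @param spatial_gradient_otus OTU ids (or indices) whose adult abundance
#'   is tilted along the plot; `gradient_slope` is the logistic slope per
#'   metre along x.
#' @param gradient_slope slope of the logistic spatial tilt.
#' @param balanced_broods if FALSE, brood sizes are drawn unbalanced with
#'   two single-larva dams, as in the study; default TRUE (balanced).
#' @param relatedness_convention `"sibclass"` (discrete sib-class coefficients) or `"tabular"`: the relatedness
#'   matrix under which larval breeding values are drawn.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_dams = 9, n_sires = 45, n_larvae = 60, n_selfed = 4,
                       n_otus = 161, n_larval_specific_otus = 93,
                       n_adult_specific_otus = 17, n_clades = 5,
                       seq_len = 300,
                       read_depth_mean = 20000, read_depth_dispersion = 0.4,
                       v = 0.9, winnowing_exponent = 2,
                       env_pool_concentration = 0.4,
                       gamma0 = log(40),
                       sigma2_a = 0.5, sigma2_e = 0.5, sigma2_m = 0,
                       spatial_gradient_otus = 1:3, gradient_slope = 0.15,
                       balanced_broods = TRUE,
                       relatedness_convention = c("sibclass", "tabular"),
                       seed = 1L) {
  relatedness_convention <- match.arg(relatedness_convention)
  if (n_selfed > n_larvae) stop("n_selfed cannot exceed n_larvae")
  if (v < 0 || v > 1) stop("vertical fidelity v must lie in [0, 1]")
  if (any(c(sigma2_a, sigma2_e, sigma2_m) < 0)) stop("variances must be >= 0")
  if (n_sires < n_dams) stop("the sire pool must contain the dams")
  if (n_larval_specific_otus + n_adult_specific_otus >= n_otus)
    stop("stage-specific OTUs must leave a shared pool")
  if (seq_len < 10) stop("seq_len must be >= 10")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a brooding mating-design pedigree
#'
#' Founder colonies are the candidate sire pool (which contains the dams).
#' Larvae are assigned to dams in roughly balanced broods; sires are drawn
#' uniformly from the candidate pool (excluding the dam, except for the
#' exactly `n_selfed` larvae forced to `sire = dam`). The pedigree is
#' guaranteed to contain at least one non-selfed full-sib pair and, for
#' more than one dam, half sibs.
#'
#' @param cfg a [sim_config()].
#' @param seed overrides `cfg$seed`.
#' @return a `pedigree`; larvae are named `L01..`, colonies `C01..`.
#' @export
simulate_pedigree <- function(cfg = sim_config(), seed = cfg$seed) {
  set.seed(as.integer(seed))
  colonies <- sprintf("C%02d", seq_len(cfg$n_sires))
  dams <- colonies[seq_len(cfg$n_dams)]
  larvae <- sprintf("L%02d", seq_len(cfg$n_larvae))
  if (cfg$balanced_broods) {
    dam_of <- rep(dams, length.out = cfg$n_larvae)
  } else {
    # study-like imbalance: two dams contribute a single larva each
    singles <- utils::head(dams, 2L)
    rest <- rep(setdiff(dams, singles), length.out = cfg$n_larvae - 2L)
    dam_of <- c(singles, rest)
  }
  dam_of <- sort(dam_of)
  sire_of <- character(cfg$n_larvae)
  for (d in unique(dam_of)) {
    idx <- which(dam_of == d)
    pool <- setdiff(colonies, d)
    # a lone colony can only self-fertilize
    sire_of[idx] <- if (length(pool)) sample(pool, length(idx), replace = TRUE)
                    else d
  }
  # force exactly n_selfed selfed larvae, spread over the first broods
  if (cfg$n_selfed > 0) {
    self_idx <- which(!duplicated(dam_of))[seq_len(min(cfg$n_selfed,
                                                       cfg$n_dams))]
    extra <- cfg$n_selfed - length(self_idx)
    if (extra > 0)
      self_idx <- c(self_idx, setdiff(seq_len(cfg$n_larvae), self_idx)[seq_len(extra)])
    sire_of[self_idx] <- dam_of[self_idx]
  }
  # guarantee a full-sib (non-selfed) pair in the largest brood
  tab <- table(dam_of)
  big <- names(tab)[which.max(tab)]
  idx <- which(dam_of == big & sire_of != dam_of)
  if (length(idx) >= 2L && sire_of[idx[1L]] != sire_of[idx[2L]])
    sire_of[idx[2L]] <- sire_of[idx[1L]]
  pedigree(c(colonies, larvae),
           c(rep(NA, length(colonies)), dam_of),
           c(rep(NA, length(colonies)), sire_of))
}

#' Simulate clade-structured OTU representative sequences
#'
#' OTUs are partitioned round-robin into `n_clades` clusters. A root
#' sequence is mutated at a high between-cluster rate to give each cluster
#' an ancestor, and each OTU mutates its cluster ancestor at a low
#' within-cluster rate, so within-cluster p-distances are smaller than
#' between-cluster distances in expectation.
#'
#' @param n_otus number of OTUs (>= 2).
#' @param seq_len sequence length (>= 10).
#' @param n_clades number of clusters.
#' @param within_rate,between_rate per-site substitution probabilities.
#' @param seed integer seed.
#' @return a `sequence_set` named `OTU1..OTUn`, plus attribute `clade`
#'   (integer cluster of each OTU).
#' @export
simulate_sequences <- function(n_otus, seq_len = 300, n_clades = 5,
                               within_rate = 0.02, between_rate = 0.2,
                               seed = 1L) {
  if (n_otus < 2) stop("need n_otus >= 2")
  if (seq_len < 10) stop("seq_len must be >= 10")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  mutate <- function(s, rate) {
    hit <- stats::runif(length(s)) < rate
    if (any(hit))
      s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1L), "")
    s
  }
  root <- sample(bases, seq_len, replace = TRUE)
  n_clades <- min(n_clades, n_otus)
  ancestors <- lapply(seq_len(n_clades), function(i) mutate(root, between_rate))
  clade <- rep(seq_len(n_clades), length.out = n_otus)
  seqs <- vapply(seq_len(n_otus), function(i)
    paste(mutate(ancestors[[clade[i]]], within_rate), collapse = ""), "")
  names(seqs) <- paste0("OTU", seq_len(n_otus))
  out <- sequence_set(seqs)
  attr(out, "clade") <- clade
  out
}

# partition of the OTU pool into larva-only / shared / adult-only ids
otu_pools <- function(cfg) {
  ids <- paste0("OTU", seq_len(cfg$n_otus))
  n_shared <- cfg$n_otus - cfg$n_larval_specific_otus - cfg$n_adult_specific_otus
  list(shared = ids[seq_len(n_shared)],
       adult_only = ids[n_shared + seq_len(cfg$n_adult_specific_otus)],
       larva_only = ids[n_shared + cfg$n_adult_specific_otus +
                          seq_len(cfg$n_larval_specific_otus)])
}

#' Simulate adult colony communities with spatial structure
#'
#' Each adult colony gets uniform coordinates in the 16 m x 40 m plot and a
#' community drawn Dirichlet-multinomial over the adult OTU pool (shared +
#' adult-only types; larva-only types are structurally absent). The shared
#' pool is dominated by the first few OTUs (the C-clade-like dominants)
#' over a long tail of background types. For OTUs listed in
#' `spatial_gradient_otus` the Dirichlet mean is tilted by a logistic
#' function of the (x, y) position; library sizes are lognormal.
#'
#' @param cfg a [sim_config()].
#' @param ped pedigree from [simulate_pedigree()] (identifies the colonies).
#' @param seed integer seed.
#' @return list with `counts` (adults x all OTUs), `coords` (data.frame
#'   `sample_id`, `x`, `y`, `size_class`).
#' @export
simulate_adults <- function(cfg, ped, seed = cfg$seed) {
  set.seed(as.integer(seed))
  adults <- ped$individual[is.na(ped$dam) & is.na(ped$sire)]
  pools <- otu_pools(cfg)
  all_ids <- paste0("OTU", seq_len(cfg$n_otus))
  pool <- c(pools$shared, pools$adult_only)
  # dominant head (the consistently abundant C-clade-like types) over a
  # geometric tail of background types; the concentration keeps the same
  # few types dominant in every colony while the tail varies
  w <- 0.93 ^ seq_along(pool)
  w[seq_len(min(3L, length(pool)))] <- w[seq_len(min(3L, length(pool)))] * 20
  base_alpha <- 80 * w / sum(w)
  x <- stats::runif(length(adults), 0, 16)
  y <- stats::runif(length(adults), 0, 40)
  grad_ids <- if (is.numeric(cfg$spatial_gradient_otus))
    paste0("OTU", cfg$spatial_gradient_otus) else cfg$spatial_gradient_otus
  grad_ids <- intersect(grad_ids, pool)
  counts <- matrix(0L, length(adults), cfg$n_otus,
                   dimnames = list(adults, all_ids))
  for (j in seq_along(adults)) {
    alpha <- base_alpha
    if (length(grad_ids) && cfg$gradient_slope != 0) {
      tilt <- 4 * stats::plogis(cfg$gradient_slope * (x[j] - 8) +
                                  0.5 * cfg$gradient_slope * (y[j] - 20))
      alpha[match(grad_ids, pool)] <- alpha[match(grad_ids, pool)] * tilt
    }
    p <- stats::rgamma(length(alpha), alpha, 1)
    p <- p / sum(p)
    depth <- round(stats::rlnorm(1L, log(cfg$read_depth_mean),
                                 cfg$read_depth_dispersion))
    counts[j, pool] <- stats::rmultinom(1L, max(depth, 100), p)[, 1L]
  }
  # every OTU of the adult pool is, by definition of an observed table,
  # detected somewhere: seed one read for any type the draw missed
  missed <- pool[colSums(counts[, pool, drop = FALSE]) == 0]
  for (o in missed) counts[sample(length(adults), 1L), o] <- 1L
  size_class <- sample(c("I", "II", "III", "IV", "V"), length(adults),
                       replace = TRUE, prob = c(0.1, 0.2, 0.35, 0.25, 0.1))
  list(counts = counts,
       coords = data.frame(sample_id = adults, x = x, y = y,
                           size_class = size_class,
                           stringsAsFactors = FALSE))
}

#' Simulate brooded larval communities under mixed-mode transmission
#'
#' Each larva's expected composition is `v * maternal + (1 - v) * env`,
#' where the maternal component is the dam's realized community restricted
#' to transmissible (non-adult-only) types and the environmental pool is a
#' single Dirichlet draw over shared + larva-only types. Breeding values
#' `a ~ N(0, sigma2_a A)` (A from the tabular relationship matrix, drawn
#' through its eigen-factorization) and an independent jitter
#' `e ~ N(0, sigma2_e)` enter the Dirichlet concentration
#' `c_l = exp(gamma0 + a_l + e_l)`, making community evenness - and hence
#' the scalar diversity trait - heritable. Counts are multinomial with
#' lognormal depth.
#'
#' @param cfg a [sim_config()].
#' @param ped pedigree.
#' @param adult_counts counts matrix from [simulate_adults()].
#' @param seed integer seed.
#' @return list with `counts` (larvae x all OTUs) and `truth` (data.frame:
#'   `sample_id`, `dam_id`, `sire_id`, `a` (breeding value), `e` (jitter),
#'   `vertical_fraction`), plus `h2_true` attribute-style element
#'   `h2_true = sigma2_a / (sigma2_a + sigma2_e (+ sigma2_m))`.
#' @export
simulate_larvae <- function(cfg, ped, adult_counts, seed = cfg$seed) {
  if (cfg$v < 0 || cfg$v > 1) stop("vertical fidelity v must lie in [0, 1]")
  set.seed(as.integer(seed))
  larvae <- ped$individual[!is.na(ped$dam)]
  dam_of <- ped$dam[match(larvae, ped$individual)]
  sire_of <- ped$sire[match(larvae, ped$individual)]
  pools <- otu_pools(cfg)
  all_ids <- colnames(adult_counts)
  larval_pool <- c(pools$shared, pools$larva_only)
  # shared environmental pool over the larval-accessible types
  env <- stats::rgamma(length(larval_pool),
                       cfg$env_pool_concentration *
                         c(rep(3, length(pools$shared)),
                           rep(1, length(pools$larva_only))), 1)
  env <- env / sum(env)
  env_full <- stats::setNames(rep(0, length(all_ids)), all_ids)
  env_full[larval_pool] <- env
  # breeding values on the evenness channel, under the chosen convention
  A <- if (cfg$relatedness_convention == "sibclass")
    relatedness_matrix_sibclass(ped, ids = larvae)
  else relatedness_tabular(ped, ids = larvae)
  ea <- eigen(unclass(A), symmetric = TRUE)
  a_val <- drop(ea$vectors %*% (sqrt(pmax(ea$values, 0)) *
                                  stats::rnorm(length(larvae)))) *
    sqrt(cfg$sigma2_a)
  e_val <- stats::rnorm(length(larvae), 0, sqrt(cfg$sigma2_e))
  m_val <- if (cfg$sigma2_m > 0) {
    md <- stats::setNames(stats::rnorm(length(unique(dam_of)), 0,
                                       sqrt(cfg$sigma2_m)), unique(dam_of))
    md[dam_of]
  } else rep(0, length(larvae))
  counts <- matrix(0L, length(larvae), length(all_ids),
                   dimnames = list(larvae, all_ids))
  reachable <- matrix(FALSE, length(larvae), length(all_ids),
                      dimnames = dimnames(counts))
  for (l in seq_along(larvae)) {
    mom <- adult_counts[dam_of[l], ]
    mom_p <- stats::setNames(rep(0, length(all_ids)), all_ids)
    transmissible <- setdiff(all_ids, pools$adult_only)
    if (sum(mom[transmissible]) > 0) {
      # winnowing: dominant maternal types are transmitted preferentially
      w <- (mom[transmissible] / sum(mom[transmissible]))^cfg$winnowing_exponent
      mom_p[transmissible] <- w / sum(w)
    }
    exp_p <- cfg$v * mom_p + (1 - cfg$v) * env_full
    conc <- exp(cfg$gamma0 + a_val[l] + e_val[l] + m_val[l])
    sup <- exp_p > 0
    reachable[l, ] <- sup
    g <- stats::rgamma(sum(sup), conc * exp_p[sup], 1)
    if (sum(g) == 0) g[which.max(exp_p[sup])] <- 1
    p <- g / sum(g)
    depth <- round(stats::rlnorm(1L, log(cfg$read_depth_mean),
                                 cfg$read_depth_dispersion))
    counts[l, sup] <- stats::rmultinom(1L, max(depth, 100), p)[, 1L]
  }
  # observed-table semantics: every OTU a larva could plausibly carry is
  # detected in >= 1 larva (an OTU table only contains detected OTUs)
  missed <- larval_pool[colSums(counts[, larval_pool, drop = FALSE]) == 0]
  for (o in missed) {
    cand <- which(reachable[, o])
    if (length(cand))
      counts[cand[sample.int(length(cand), 1L)], o] <- 1L
  }
  h2_true <- cfg$sigma2_a /
    (cfg$sigma2_a + cfg$sigma2_e + if (cfg$sigma2_m > 0) cfg$sigma2_m else 0)
  list(counts = counts,
       truth = data.frame(sample_id = larvae, dam_id = dam_of,
                          sire_id = sire_of, a = a_val, e = e_val,
                          vertical_fraction = cfg$v,
                          stringsAsFactors = FALSE),
       h2_true = h2_true)
}

#' Simulate a full synthetic dataset
#'
#' Runs [simulate_pedigree()], [simulate_sequences()], [simulate_adults()]
#' and [simulate_larvae()] and assembles an [otu_table] over adults and
#' larvae.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (sub-seeds are derived deterministically).
#' @return list of class `sim_output`: `otu_table`, `sequences`,
#'   `pedigree`, `truth` (with true breeding values and `h2_true`).
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = cfg$seed) {
  seed <- as.integer(seed)
  ped <- simulate_pedigree(cfg, seed = seed)
  seqs <- simulate_sequences(cfg$n_otus, cfg$seq_len, cfg$n_clades,
                             seed = seed + 1L)
  ad <- simulate_adults(cfg, ped, seed = seed + 2L)
  la <- simulate_larvae(cfg, ped, ad$counts, seed = seed + 3L)
  counts <- rbind(ad$counts, la$counts)
  meta <- rbind(
    data.frame(sample_id = rownames(ad$counts), life_stage = "adult",
               dam_id = NA, sire_id = NA,
               size_class = ad$coords$size_class,
               x = ad$coords$x, y = ad$coords$y, stringsAsFactors = FALSE),
    data.frame(sample_id = la$truth$sample_id, life_stage = "larva",
               dam_id = la$truth$dam_id, sire_id = la$truth$sire_id,
               size_class = NA, x = NA, y = NA, stringsAsFactors = FALSE))
  structure(list(otu_table = otu_table(counts, meta),
                 sequences = seqs, pedigree = ped,
                 truth = list(larvae = la$truth, h2_true = la$h2_true,
                              config = cfg)),
            class = "sim_output")
}

#' Simulate a trait directly on a pedigree (no community layer)
#'
#' Clean validation channel for the animal model:
#' `y = mu + a + m + e` with `a ~ N(0, sigma2_a A)`, per-dam iid maternal
#' effects and iid residuals.
#'
#' Breeding values are drawn with covariance `sigma2_a * A` under the
#' requested relatedness convention; the discrete sib-class convention is the
#' default (projected to the nearest PSD matrix when needed), the recursive
#' tabular matrix is the alternative.
#'
#' @param ped a `pedigree`.
#' @param mu intercept.
#' @param sigma2_a,sigma2_e,sigma2_m variance components (>= 0).
#' @param ids individuals to phenotype (default: all non-founders).
#' @param convention `"sibclass"` (discrete sib-class coefficients) or
#'   `"tabular"`.
#' @param seed integer seed.
#' @return list: `y` (named trait vector), `a` (true breeding values),
#'   `h2_true`, `A` (the relationship matrix used), `dam_ids`.
#' @export
simulate_trait_direct <- function(ped, mu = 0, sigma2_a = 1, sigma2_e = 1,
                                  sigma2_m = 0, ids = NULL,
                                  convention = c("sibclass", "tabular"),
                                  seed = 1L) {
  if (any(c(sigma2_a, sigma2_e, sigma2_m) < 0)) stop("variances must be >= 0")
  convention <- match.arg(convention)
  set.seed(as.integer(seed))
  if (is.null(ids)) ids <- ped$individual[!is.na(ped$dam) | !is.na(ped$sire)]
  A <- if (convention == "sibclass") relatedness_matrix_sibclass(ped, ids = ids)
       else relatedness_tabular(ped, ids = ids)
  n <- length(ids)
  ea <- eigen(unclass(A), symmetric = TRUE)
  a <- drop(ea$vectors %*% (sqrt(pmax(ea$values, 0)) * stats::rnorm(n))) *
    sqrt(sigma2_a)
  dam_ids <- ped$dam[match(ids, ped$individual)]
  m <- if (sigma2_m > 0) {
    md <- stats::setNames(stats::rnorm(length(unique(dam_ids)), 0, sqrt(sigma2_m)),
                          unique(dam_ids))
    unname(md[dam_ids])
  } else rep(0, n)
  e <- stats::rnorm(n, 0, sqrt(sigma2_e))
  y <- stats::setNames(mu + a + m + e, ids)
  denom <- sigma2_a + sigma2_e + if (sigma2_m > 0) sigma2_m else 0
  list(y = y, a = stats::setNames(a, ids),
       h2_true = if (denom > 0) sigma2_a / denom else NA_real_,
       A = A, dam_ids = dam_ids)
}
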