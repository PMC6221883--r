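# small in-code fixtures shared across test files

# 3 samples x 2 OTUs with adult/larva metadata
tiny_table <- function() {
  counts <- matrix(c(10L, 0L, 5L,
                     2L, 8L, 5L), nrow = 3,
                   dimnames = list(c("A1", "A2", "L1"), c("OTU1", "OTU2")))
  meta <- data.frame(sample_id = c("A1", "A2", "L1"),
                     life_stage = c("adult", "adult", "larva"),
                     dam_id = c(NA, NA, "A1"), sire_id = c(NA, NA, "A2"),
                     size_class = c("I", "II", NA),
                     x = c(0, 1, NA), y = c(0, 2, NA))
  otu_table(counts, meta)
}

# two founders, one outcrossed child, one selfed child
tiny_pedigree <- function() {
  pedigree(individual = c("A", "B", "C", "D"),
           dam = c(NA, NA, "A", "A"),
           sire = c(NA, NA, "B", "A"))
}

# nuclear families: dams D1,D2; sires S1,S2; full sibs, half sibs, selfed
family_pedigree <- function() {
  pedigree(
    individual = c("D1", "D2", "S1", "S2",
                   "F1", "F2",      # full sibs D1 x S1
                   "H1",            # half sib via D1 (D1 x S2)
                   "G1",            # unrelated to F's (D2 x S2)
                   "X1", "X2"),     # selfed offspring of D2
    dam  = c(NA, NA, NA, NA, "D1", "D1", "D1", "D2", "D2", "D2"),
    sire = c(NA, NA, NA, NA, "S1", "S1", "S2", "S2", "D2", "D2"))
}

# validation pedigree for variance-component recovery: selfed sibships are
# clone-like blocks under the sib-class relatedness convention (all pairwise
# coefficients 1 within a brood), so within-brood contrasts pin the residual
# variance and between-brood contrasts pin the additive variance
selfed_sibship_pedigree <- function(n_fam = 20, k = 4) {
  par <- sprintf("P%02d", seq_len(n_fam))
  kids <- sprintf("K%03d", seq_len(n_fam * k))
  pedigree(c(par, kids), c(rep(NA, n_fam), rep(par, each = k)),
           c(rep(NA, n_fam), rep(par, each = k)))
}

# validation pedigree for the maternal-effect DIC comparison: each brood
# holds a selfed block plus a full-sib block by an outside sire, so a
# maternal effect (common to both blocks) is separable from the additive
# block structure
maternal_check_pedigree <- function(n_dams = 30, k_self = 5, k_full = 5) {
  dams <- sprintf("D%02d", seq_len(n_dams))
  sires <- sprintf("S%02d", seq_len(n_dams))
  n <- n_dams * (k_self + k_full)
  kids <- sprintf("K%03d", seq_len(n))
  dam_of <- rep(dams, each = k_self + k_full)
  sire_of <- character(n)
  for (b in seq_len(n_dams)) {
    idx <- (b - 1) * (k_self + k_full) + seq_len(k_self + k_full)
    sire_of[idx] <- c(rep(dams[b], k_self), rep(sires[b], k_full))
  }
  pedigree(c(dams, sires, kids), c(rep(NA, 2 * n_dams), dam_of),
           c(rep(NA, 2 * n_dams), sire_of))
}

# independent brute-force BH step-up oracle
bh_oracle <- function(p) {
  ok <- !is.na(p)
  m <- sum(ok)
  adj <- rep(NA_real_, length(p))
  if (m == 0L) return(adj)
  ord <- order(p[ok])
  ps <- p[ok][ord]
  a <- numeric(m)
  for (i in seq_len(m)) a[i] <- min(ps[i:m] * m / (i:m), 1)
  out <- numeric(m); out[ord] <- a
  adj[ok] <- out
  adj
}

# brute-force one-way PERMANOVA pseudo-F from a distance matrix
permanova_f_oracle <- function(D, labels) {
  D <- as.matrix(D); n <- nrow(D); g <- factor(labels)
  ss_tot <- sum(D[upper.tri(D)]^2) / n
  ss_w <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    if (length(idx) > 1) {
      sub <- D[idx, idx, drop = FALSE]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]^2) / length(idx)
    }
  }
  ss_b <- ss_tot - ss_w
  (ss_b / (nlevels(g) - 1)) / (ss_w / (n - nlevels(g)))
}

# gene-dropping Monte-Carlo estimate of the additive relationship between
# two pedigree members: 2 * P(random alleles IBD)
gene_drop_relatedness <- function(ped, id_a, id_b, n_drops = 1e5, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  di <- match(ped$dam, ped$individual)
  si <- match(ped$sire, ped$individual)
  # allele matrices: n_drops x n, two per individual
  al1 <- matrix(0L, n_drops, n); al2 <- matrix(0L, n_drops, n)
  next_allele <- 1L
  for (j in seq_len(n)) {
    if (is.na(di[j]) && is.na(si[j])) {
      al1[, j] <- next_allele; al2[, j] <- next_allele + 1L
      next_allele <- next_allele + 2L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      al1[, j] <- ifelse(pick, al1[, di[j]], al2[, di[j]])
      pick <- stats::runif(n_drops) < 0.5
      al2[, j] <- ifelse(pick, al1[, si[j]], al2[, si[j]])
    }
  }
  ia <- match(id_a, ped$individual); ib <- match(id_b, ped$individual)
  # kinship: prob a random allele from a is IBD to a random allele from b
  kin <- (al1[, ia] == al1[, ib]) + (al1[, ia] == al2[, ib]) +
    (al2[, ia] == al1[, ib]) + (al2[, ia] == al2[, ib])
  2 * mean(kin / 4)
}
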