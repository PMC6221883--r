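test_that("the default mating design mirrors the study counts", {
  cfg <- sim_config()
  ped <- simulate_pedigree(cfg, seed = 1)
  larvae <- ped[!is.na(ped$dam), ]
  expect_equal(nrow(larvae), 60)
  expect_equal(sum(larvae$dam == larvae$sire), 4)
  expect_equal(length(unique(larvae$dam)), 9)
  expect_true(all(larvae$sire %in% sprintf("C%02d", 1:45)))
  # half sibs exist (broods > 1) and at least one non-selfed full-sib pair
  key <- paste(larvae$dam, larvae$sire)
  expect_true(any(duplicated(key[larvae$dam != larvae$sire])))
  expect_true(any(table(larvae$dam) > 1))
  expect_error(sim_config(n_selfed = 99), "n_selfed")
})

test_that("degenerate designs produce the forced sib structures", {
  cfg <- sim_config(n_dams = 1, n_sires = 2, n_larvae = 4, n_selfed = 0)
  ped <- simulate_pedigree(cfg, seed = 3)
  larvae <- ped[!is.na(ped$dam), ]
  expect_true(all(larvae$dam == larvae$dam[1]))
  # single dam + single candidate sire: every larva is a full sib
  cfg1 <- sim_config(n_dams = 1, n_sires = 1, n_larvae = 5, n_selfed = 0)
  ped1 <- simulate_pedigree(cfg1, seed = 4)
  l1 <- ped1[!is.na(ped1$dam), ]
  expect_equal(length(unique(paste(l1$dam, l1$sire))), 1L)
})

test_that("simulated sequences are clade-structured and reproducible", {
  s0 <- simulate_sequences(2, seq_len = 50, n_clades = 1, within_rate = 0,
                           seed = 5)
  expect_equal(unclass(s0)[[1]], unclass(s0)[[2]])
  expect_equal(p_distance(s0[[1]], s0[[2]]), 0)
  # within-cluster distances smaller than between, on average over reps
  wins <- vapply(1:20, function(r) {
    ss <- simulate_sequences(8, seq_len = 120, n_clades = 2,
                             within_rate = 0.02, between_rate = 0.3,
                             seed = 100 + r)
    cl <- attr(ss, "clade")
    d <- 1 - similarity_matrix(ss)
    same <- outer(cl, cl, "==") & upper.tri(d)
    diff <- outer(cl, cl, "!=") & upper.tri(d)
    mean(d[diff]) > mean(d[same])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
  # byte-identical FASTA on rerun with the same seed
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(simulate_sequences(10, 60, seed = 9), f1)
  write_fasta(simulate_sequences(10, 60, seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(simulate_sequences(1, 50), "n_otus")
  expect_error(simulate_sequences(5, 5), "seq_len")
})

test_that("adult communities respect the OTU pools and spatial gradients", {
  cfg <- sim_config()
  ped <- simulate_pedigree(cfg, seed = 2)
  ad <- simulate_adults(cfg, ped, seed = 2)
  pools <- divherit:::otu_pools(cfg)
  expect_true(all(colSums(ad$counts[, pools$larva_only]) == 0))
  expect_true(all(colSums(ad$counts[, pools$adult_only]) > 0))
  expect_true(all(ad$coords$x >= 0 & ad$coords$x <= 16))
  expect_true(all(ad$coords$y >= 0 & ad$coords$y <= 40))
  # no gradient -> no abundance-coordinate correlation (median over reps)
  flat <- sim_config(gradient_slope = 0)
  rho0 <- vapply(1:15, function(r) {
    a <- simulate_adults(flat, ped, seed = 300 + r)
    rel <- a$counts[, "OTU1"] / rowSums(a$counts)
    suppressWarnings(stats::cor(a$coords$x, rel, method = "spearman"))
  }, numeric(1))
  expect_lt(abs(stats::median(rho0)), 0.2)
  # strong gradient on OTU1 along x -> clear positive rank correlation
  steep <- sim_config(spatial_gradient_otus = 1, gradient_slope = 1.2)
  rho1 <- vapply(1:15, function(r) {
    a <- simulate_adults(steep, ped, seed = 400 + r)
    rel <- a$counts[, "OTU1"] / rowSums(a$counts)
    suppressWarnings(stats::cor(a$coords$x, rel, method = "spearman"))
  }, numeric(1))
  expect_gt(stats::median(rho1), 0.5)
})

test_that("larval communities mix maternal and environmental sources", {
  cfg <- sim_config()
  ped <- simulate_pedigree(cfg, seed = 2)
  ad <- simulate_adults(cfg, ped, seed = 2)
  pools <- divherit:::otu_pools(cfg)
  # full vertical fidelity: no larva-only types, composition tracks the dam
  vert <- sim_config(v = 1)
  la1 <- simulate_larvae(vert, ped, ad$counts, seed = 7)
  expect_true(all(colSums(la1$counts[, pools$larva_only]) == 0))
  expect_true(all(colSums(la1$counts[, pools$adult_only]) == 0))
  # mixed transmission: larva-only types present, adult-only still absent
  la2 <- simulate_larvae(cfg, ped, ad$counts, seed = 7)
  expect_true(all(colSums(la2$counts[, pools$larva_only]) > 0))
  expect_true(all(colSums(la2$counts[, pools$adult_only]) == 0))
  expect_equal(la2$h2_true,
               cfg$sigma2_a / (cfg$sigma2_a + cfg$sigma2_e))
})

test_that("v = 0 decouples larval communities from dam identity", {
  cfg0 <- sim_config(v = 0, sigma2_a = 0, sigma2_e = 0.1)
  ped <- simulate_pedigree(cfg0, seed = 2)
  ad <- simulate_adults(cfg0, ped, seed = 2)
  ps <- vapply(1:9, function(r) {
    la <- simulate_larvae(cfg0, ped, ad$counts, seed = 600 + r)
    rel <- la$counts / rowSums(la$counts)
    keep <- colSums(rel) > 0
    D <- bray_curtis(rel[, keep])
    permanova(D, la$truth$dam_id, n_perm = 199, seed = r)$p
  }, numeric(1))
  expect_gt(stats::median(ps), 0.05)
  # and with strong vertical fidelity dam identity does structure larvae
  cfg9 <- sim_config(v = 0.9, sigma2_a = 0, sigma2_e = 0.1)
  ad9 <- simulate_adults(cfg9, ped, seed = 2)
  ps9 <- vapply(1:9, function(r) {
    la <- simulate_larvae(cfg9, ped, ad9$counts, seed = 700 + r)
    rel <- la$counts / rowSums(la$counts)
    keep <- colSums(rel) > 0
    D <- bray_curtis(rel[, keep])
    permanova(D, la$truth$dam_id, n_perm = 199, seed = r)$p
  }, numeric(1))
  expect_lt(stats::median(ps9), 0.05)
})

test_that("direct trait simulation honours its variance components", {
  ped <- simulate_pedigree(sim_config(), seed = 2)
  # all variances zero: constant trait at mu
  td0 <- simulate_trait_direct(ped, mu = 4, sigma2_a = 0, sigma2_e = 0,
                               seed = 11)
  expect_true(all(td0$y == 4))
  # same seed, same vector
  tda <- simulate_trait_direct(ped, sigma2_a = 1, sigma2_e = 2, seed = 12)
  tdb <- simulate_trait_direct(ped, sigma2_a = 1, sigma2_e = 2, seed = 12)
  expect_identical(tda$y, tdb$y)
  expect_equal(tda$h2_true, 1 / 3)
  # unrelated individuals (A = I): var(y) ~ sigma2_a + sigma2_e at large n,
  # built as independent founder-pair crosses
  n <- 2000
  dams <- sprintf("DM%05d", 1:n); sires <- sprintf("SR%05d", 1:n)
  unrel <- pedigree(c(dams, sires, sprintf("I%05d", 1:n)),
                    c(rep(NA, 2 * n), dams), c(rep(NA, 2 * n), sires))
  td <- simulate_trait_direct(unrel, sigma2_a = 0.6, sigma2_e = 0.4,
                              convention = "sibclass", seed = 13)
  expect_lt(abs(stats::var(td$y) - 1), 0.05)
})

test_that("assembled datasets satisfy the stage-partition invariants", {
  sim <- simulate_dataset(sim_config(), seed = 1)
  part <- shared_unique_partition(sim$otu_table)
  cfg <- sim$truth$config
  expect_equal(unname(part$counts["larva_only"]), cfg$n_larval_specific_otus)
  expect_equal(unname(part$counts["adult_only"]), cfg$n_adult_specific_otus)
  expect_equal(sum(part$counts), cfg$n_otus)
  expect_equal(length(sim$sequences), cfg$n_otus)
  expect_equal(sim$truth$h2_true, cfg$sigma2_a / (cfg$sigma2_a + cfg$sigma2_e))
  # reproducible end to end
  sim2 <- simulate_dataset(sim_config(), seed = 1)
  expect_identical(sim$otu_table$counts, sim2$otu_table$counts)
})
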