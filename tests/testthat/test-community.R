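test_that("Bray-Curtis distances match hand arithmetic and edge cases", {
  x <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0),
             d = c(2, 0, 0), e = c(0, 0, 3))
  D <- bray_curtis(x)
  expect_equal(D["a", "b"], 0.5)       # |1-0|+|1-1|+|0-1| over 4
  expect_equal(D["a", "c"], 0)         # identical rows
  expect_equal(D["d", "e"], 1)         # disjoint supports
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
  # invariant to appending an all-zero OTU column
  expect_equal(bray_curtis(cbind(x, zero = 0)), D)
  expect_error(bray_curtis(rbind(a = c(1, 2), bad = c(0, 0))), "bad")
})

test_that("PCoA reproduces Euclidean geometry and reports negative eigenvalues", {
  set.seed(60)
  pts <- matrix(stats::rnorm(7 * 3), 7)
  rownames(pts) <- paste0("s", 1:7)
  D <- as.matrix(stats::dist(pts))
  emb <- pcoa(D)
  expect_lt(max(abs(as.matrix(stats::dist(emb$points)) - D)), 1e-8)
  expect_equal(ncol(emb$imaginary_points), 0)
  # three equidistant points: two equal positive eigenvalues
  D3 <- matrix(1, 3, 3) - diag(3)
  dimnames(D3) <- list(letters[1:3], letters[1:3])
  e3 <- pcoa(D3)$eigenvalues
  expect_equal(e3[1], e3[2])
  expect_gt(e3[1], 0)
  # duplicated samples are coincident in the embedding
  D4 <- as.matrix(stats::dist(pts[c(1, 1, 2, 3), ]))
  emb4 <- pcoa(D4)
  expect_lt(max(abs(emb4$points[1, ] - emb4$points[2, ])), 1e-8)
  # Bray-Curtis typically yields negative eigenvalues, which are retained
  set.seed(61)
  xx <- matrix(stats::rpois(12 * 6, 8), 12)
  rownames(xx) <- paste0("q", 1:12)
  ebc <- pcoa(bray_curtis(xx))
  expect_lt(min(ebc$eigenvalues), 0)
  expect_equal(ncol(ebc$imaginary_points), sum(ebc$eigenvalues < -max(abs(ebc$eigenvalues)) * 1e-9))
})

test_that("PERMANOVA matches the brute-force statistic and separates clusters", {
  set.seed(62)
  x <- rbind(matrix(stats::rnorm(30, 0), 10), matrix(stats::rnorm(30, 8), 10))
  rownames(x) <- paste0("s", 1:20)
  D <- as.matrix(stats::dist(x))
  g <- rep(c("u", "v"), each = 10)
  res <- permanova(D, g, n_perm = 199, seed = 1)
  expect_equal(res$f, permanova_f_oracle(D, g))
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 18)
  expect_gt(res$r2, 0.9)
  expect_equal(res$p, 1 / (199 + 1))
  expect_error(permanova(D, rep("one", 20)), "two groups")
})

test_that("PERMANOVA p-values are calibrated under the null", {
  set.seed(63)
  rejections <- vapply(1:200, function(r) {
    x <- matrix(stats::rnorm(10 * 4), 10)
    rownames(x) <- paste0("s", 1:10)
    D <- as.matrix(stats::dist(x))
    permanova(D, rep(c("a", "b"), each = 5), n_perm = 99, seed = r)$p <= 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.015)
  expect_lt(mean(rejections), 0.10)
})

test_that("dispersion test flags heterogeneous spread, not location", {
  set.seed(64)
  # same internal geometry, shifted location: no dispersion difference
  base <- matrix(stats::rnorm(10 * 3), 10)
  x <- rbind(base, base + 5)
  rownames(x) <- paste0("s", 1:20)
  g <- rep(c("a", "b"), each = 10)
  ps <- vapply(1:7, function(r) {
    noise <- matrix(stats::rnorm(20 * 3, 0, 0.05), 20)
    betadisper_test(as.matrix(stats::dist(x + noise)), g, n_perm = 199,
                    seed = r)$p
  }, numeric(1))
  expect_gt(stats::median(ps), 0.05)
  # one group with 5x the spread: detected
  ps2 <- vapply(1:7, function(r) {
    y <- rbind(matrix(stats::rnorm(10 * 3, 0, 1), 10),
               matrix(stats::rnorm(10 * 3, 0, 5), 10))
    rownames(y) <- paste0("s", 1:20)
    betadisper_test(as.matrix(stats::dist(y)), g, n_perm = 199, seed = r)$p
  }, numeric(1))
  expect_lt(stats::median(ps2), 0.05)
  # identical duplicated samples: all centroid distances zero -> NA + warning
  z <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 6), d = c(5, 6))
  expect_warning(res0 <- betadisper_test(as.matrix(stats::dist(z)),
                                         c("g1", "g1", "g2", "g2"),
                                         n_perm = 49, seed = 1),
                 "undefined")
  expect_true(is.na(res0$f))
  # singleton groups are excluded with a warning (the remaining duplicated
  # groups then also warn about undefined dispersion)
  w <- testthat::capture_warnings(
    betadisper_test(as.matrix(stats::dist(rbind(z, e = c(9, 9)))),
                    c("g1", "g1", "g2", "g2", "g3"), n_perm = 49, seed = 1))
  expect_match(w, "singleton", all = FALSE)
})

test_that("stage partition and prevalence network follow their thresholds", {
  tab <- tiny_table()
  part <- shared_unique_partition(tab)
  # OTU1: adults 10, larvae 5 -> shared; OTU2: adults 10, larvae 5 -> shared
  expect_equal(unname(part$counts), c(2, 0, 0))
  # hand-built table with stage-specific OTUs
  counts <- matrix(c(9L, 0L, 0L, 4L, 3L, 0L, 0L, 0L, 7L), nrow = 3,
                   dimnames = list(c("ad", "l1", "l2"),
                                   c("adonly", "both", "larvonly")))
  counts["ad", "both"] <- 2L
  meta <- data.frame(sample_id = c("ad", "l1", "l2"),
                     life_stage = c("adult", "larva", "larva"),
                     dam_id = c(NA, "ad", "ad"))
  tab2 <- otu_table(counts, meta)
  p2 <- shared_unique_partition(tab2)
  expect_equal(p2$adult_only, "adonly")
  expect_equal(p2$larva_only, "larvonly")
  expect_equal(p2$shared, "both")

  # prevalence network: 2 of 4 larvae kept at 0.5, 1 of 4 dropped
  k <- matrix(0L, 4, 3, dimnames = list(paste0("L", 1:4),
                                        c("half", "quarter", "all")))
  k[, "half"] <- c(3L, 2L, 0L, 0L)
  k[, "quarter"] <- c(5L, 0L, 0L, 0L)
  k[, "all"] <- c(1L, 1L, 1L, 1L)
  meta4 <- data.frame(sample_id = paste0("L", 1:4), life_stage = "larva",
                      dam_id = "D1")
  net <- prevalence_network(otu_table(k, meta4), threshold = 0.5)
  expect_true("half" %in% net$otu_id)
  expect_false("quarter" %in% net$otu_id)
  expect_true(net$core[net$otu_id == "all"])
  expect_false(net$core[net$otu_id == "half"])
  # edge set shrinks monotonically with the threshold
  net9 <- prevalence_network(otu_table(k, meta4), threshold = 0.9)
  expect_true(all(paste(net9$brood, net9$otu_id) %in%
                    paste(net$brood, net$otu_id)))
})

test_that("Spearman matrices handle monotone, reversed and tied data", {
  x <- cbind(up = c(1, 2, 3, 4, 5), mono = c(2, 4, 9, 16, 25),
             down = c(10, 8, 5, 4, 1), tied = c(1, 1, 2, 2, 3))
  sp <- spearman_pairs(x)
  expect_equal(sp$rho["up", "mono"], 1)
  expect_equal(sp$rho["up", "down"], -1)
  # ties use average ranks: brute-force check
  r1 <- rank(x[, "up"]); r2 <- rank(x[, "tied"])
  expect_equal(sp$rho["up", "tied"], stats::cor(r1, r2))
  expect_warning(spc <- spearman_pairs(cbind(x, flat = rep(1, 5))),
                 "constant")
  expect_true(all(is.na(spc$rho["flat", ])))
  expect_error(spearman_pairs(x[1:2, ]), "3 samples")
})

test_that("spatial models recover planted gradients on centered coordinates", {
  set.seed(65)
  x <- stats::runif(40, 0, 16); y <- stats::runif(40, 0, 40)
  # abundance = (a + b x)^2 so sqrt() is exactly linear in x
  ab <- (2 + 0.5 * x)^2
  fit <- suppressWarnings(spatial_linear_model(ab, x, y))  # exact fit warns
  cf <- fit$coefficients
  expect_lt(abs(cf$estimate[cf$term == "xc"] - 0.5), 1e-8)
  expect_lt(cf$p[cf$term == "xc"], 1e-10)
  # intercept equals the mean response at the centroid
  expect_equal(cf$estimate[cf$term == "(Intercept)"],
               mean(stats::fitted(fit$fit)))
  # no spatial signal: slope p roughly uniform over replicates
  ps <- vapply(1:20, function(r) {
    set.seed(100 + r)
    ab0 <- stats::rlnorm(40)
    spatial_linear_model(ab0, x, y)$coefficients$p[2]
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.7)
  expect_error(spatial_linear_model(ab[1:4], x[1:4], y[1:4]), "6 samples")
  expect_error(spatial_linear_model(ab, x, 2 * x), "collinear")
})

test_that("size-class differential abundance pools BH across pairs", {
  set.seed(66)
  n_per <- 4
  cls <- rep(c("I", "II", "III"), each = n_per)
  k <- matrix(rnbinom(3 * n_per * 20, mu = 60, size = 10), nrow = 3 * n_per)
  # plant a strong effect: OTU1 much higher in class III
  k[cls == "III", 1] <- k[cls == "III", 1] + 600L
  rownames(k) <- paste0("a", seq_len(nrow(k)))
  colnames(k) <- paste0("o", 1:20)
  meta <- data.frame(sample_id = rownames(k), life_stage = "adult",
                     size_class = cls)
  tab <- otu_table(k, meta)
  res <- sizeclass_da(tab)
  expect_setequal(unique(paste(res$class_a, res$class_b)),
                  c("I II", "I III", "II III"))
  hit <- res[res$otu_id == "o1" & res$class_b == "III", ]
  expect_true(all(hit$significant))
  expect_true(all(res$p_adjusted >= res$p_value, na.rm = TRUE))
  # singleton class excluded with warning
  meta2 <- meta; meta2$size_class[1] <- "V"
  expect_warning(sizeclass_da(otu_table(k, meta2)), "singleton")
})
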