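test_that("diversity statistics match hand-computed values", {
  # one locus, both individuals heterozygous: H_O = 1, H_E = (4/3)*0.5
  G <- matrix(c(1, 1), 2, 1)
  d <- diversity(genotype_matrix(G, c("P", "P")))
  expect_equal(d$populations$H_O, 1)
  expect_equal(d$populations$H_E, 2 / 3)
  expect_equal(d$populations$pi_S, 2 / 3)   # per-SNP pairwise proportion
  # monomorphic locus: all zero
  d0 <- diversity(genotype_matrix(matrix(0, 3, 1), rep("P", 3)))
  expect_equal(unlist(d0$populations[, c("H_O", "H_E", "pi_S")]),
               c(H_O = 0, H_E = 0, pi_S = 0))
})

test_that("pi matches exhaustive pairwise enumeration on a toy table", {
  G <- matrix(c(0, 1, 2,
                2, 2, 1,
                0, 0, 1), 3, 3)
  d <- diversity(genotype_matrix(G, rep("P", 3)))
  # brute force: per locus, compare all C(6,2) allele pairs
  pis <- apply(G, 2, function(g) {
    alleles <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
    pairs <- combn(6, 2)
    mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
  })
  expect_equal(d$populations$pi_S, mean(pis), tolerance = 1e-12)
  hos <- apply(G, 2, function(g) mean(g == 1))
  expect_equal(d$populations$H_O, mean(hos), tolerance = 1e-12)
})

test_that("the larger western deme carries more per-SNP diversity", {
  s <- inference_settings(seed = 1)
  spec <- synthetic_spec("M6", reference_history(), n_loci = 400L,
                         missing_rate = 0,
                         pops = data.frame(name = c("W1", "E1"), n = 8L,
                                           lineage = c("west", "east"),
                                           alpha = NA_real_),
                         settings = s)
  pis <- vapply(1:3, function(i) {
    ds <- generate_dataset(spec, seed = 500 + i)
    d <- diversity(ds$geno)$lineages
    c(d$pi_S[d$lineage == "west"], d$pi_S[d$lineage == "east"])
  }, numeric(2))
  expect_gt(mean(pis[1, ]), mean(pis[2, ]))
})

test_that("AMOVA matches a brute-force pairwise-distance computation", {
  set.seed(13)
  G <- matrix(sample(0:2, 12 * 20, replace = TRUE), 12, 20)
  pops <- rep(c("p1", "p2", "p3", "p4"), each = 3)
  groups <- c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2")
  res <- amova(genotype_matrix(G, pops), groups, n_perm = 0)

  # independent route: classical nested ANOVA sums of squares (deviations
  # from centroids of the dosage vectors), not the pairwise-distance form
  ss_set <- function(idx) {
    X <- G[idx, , drop = FALSE]
    sum(sweep(X, 2, colMeans(X))^2)
  }
  ss_tot <- ss_set(1:12)
  ss_wp <- sum(vapply(unique(pops), function(p) ss_set(which(pops == p)),
                      numeric(1)))
  grp <- groups[pops]
  ss_wg <- sum(vapply(unique(grp), function(g) ss_set(which(grp == g)),
                      numeric(1)))
  ss_ag <- ss_tot - ss_wg
  ss_ap <- ss_wg - ss_wp
  expect_equal(unname(res$ss["total"]), ss_tot, tolerance = 1e-12)
  expect_equal(unname(res$ss["among_groups"]), ss_ag, tolerance = 1e-12)
  expect_equal(unname(res$ss["among_pops_within"]), ss_ap, tolerance = 1e-12)
  expect_equal(unname(res$ss["within_pops"]), ss_wp, tolerance = 1e-12)
  # balanced design: n' = n'' = 3, n''' = 6
  ms <- c(ss_ag / 1, ss_ap / 2, ss_wp / 8)
  s2c <- ms[3]; s2b <- (ms[2] - s2c) / 3; s2a <- (ms[1] - s2c - 3 * s2b) / 6
  expect_equal(unname(res$sigma2), c(s2a, s2b, s2c), tolerance = 1e-12)
  expect_equal(unname(res$phi["PHI_ST"]), (s2a + s2b) / (s2a + s2b + s2c),
               tolerance = 1e-12)
  # components sum to the total variance of the distance formulation
  expect_equal(sum(res$sigma2),
               s2a + s2b + s2c, tolerance = 1e-12)
  # supplying the Euclidean distance matrix directly gives the same result
  res_d <- amova(dist(G), groups, n_perm = 0, popmap = pops)
  expect_equal(res_d$sigma2, res$sigma2, tolerance = 1e-12)
  expect_equal(res_d$phi, res$phi, tolerance = 1e-12)
})

test_that("AMOVA one-level partition agrees with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(29)
  G <- matrix(sample(0:2, 10 * 15, replace = TRUE), 10, 15)
  pops <- rep(c("a", "b"), each = 5)
  res <- amova(genotype_matrix(G, pops), groups = c(a = "g", b = "g"),
               n_perm = 0)
  ad <- vegan::adonis2(dist(G) ~ factor(pops), permutations = 1)
  expect_equal(unname(res$ss["among_pops_within"]), ad$SumOfSqs[1],
               tolerance = 1e-8)
  expect_equal(unname(res$ss["within_pops"]), ad$SumOfSqs[2],
               tolerance = 1e-8)
})

test_that("AMOVA handles fixation and degenerate data", {
  # two populations fixed for alternative alleles: PHI_ST = 1
  G <- rbind(matrix(0L, 4, 10), matrix(2L, 4, 10))
  res <- amova(genotype_matrix(G, rep(c("a", "b"), each = 4)),
               groups = c(a = "ga", b = "gb"), n_perm = 50, seed = 1)
  expect_equal(unname(res$phi["PHI_ST"]), 1, tolerance = 1e-12)
  expect_equal(unname(res$sigma2["within_pops"]), 0, tolerance = 1e-12)
  # all individuals identical: NaN Phi with a flag
  G2 <- matrix(1L, 6, 5)
  res2 <- amova(genotype_matrix(G2, rep(c("a", "b"), each = 3)),
                groups = c(a = "ga", b = "gb"), n_perm = 10)
  expect_true(res2$degenerate)
  expect_true(all(is.nan(res2$phi) | is.na(res2$phi)))
  # errors
  expect_error(amova(genotype_matrix(G2, rep("a", 6)), c(a = "g")),
               "two populations")
  expect_error(amova(genotype_matrix(G2, rep(c("a", "b"), each = 3)),
                     c(a = "g")), "assigned to a group")
})

test_that("AMOVA permutation p-values are significant under real structure", {
  set.seed(91)
  # strong two-group structure
  G <- rbind(matrix(rbinom(6 * 40, 2, 0.05), 6, 40),
             matrix(rbinom(6 * 40, 2, 0.95), 6, 40))
  pops <- rep(c("p1", "p2", "p3", "p4"), each = 3)
  groups <- c(p1 = "gw", p2 = "gw", p3 = "ge", p4 = "ge")
  res <- amova(genotype_matrix(G, pops), groups, n_perm = 200, seed = 2)
  expect_lt(res$p_values["PHI_ST"], 0.05)
  expect_gte(res$p_values["PHI_ST"], 1 / 201)
})

test_that("Mantel statistic hits its closed-form extremes", {
  set.seed(17)
  pts <- matrix(runif(10), 5, 2)
  A <- as.matrix(dist(pts))
  expect_equal(mantel(A, A, n_perm = 9, seed = 1)$r, 1)
  B <- max(A) + 1 - A; diag(B) <- 0
  expect_equal(mantel(A, B, n_perm = 9, seed = 1)$r, -1)
  # constant matrix flagged
  C <- matrix(1, 5, 5); diag(C) <- 0; C[] <- 0
  expect_true(is.nan(mantel(A, C, n_perm = 9)$r))
  expect_error(mantel(A, as.matrix(dist(pts[1:4, ]))), "mismatch")
})

test_that("exact Mantel p equals exhaustive enumeration", {
  set.seed(23)
  A <- as.matrix(dist(runif(4)))
  B <- as.matrix(dist(runif(4)))
  res <- mantel(A, B, exact = TRUE)
  expect_identical(res$n_perm, 24L)
  # independent enumeration: generate all 24 orderings with expand.grid
  ords <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  ords <- ords[apply(ords, 1, function(o) length(unique(o)) == 4), ]
  ut <- upper.tri(A)
  r_obs <- cor(A[ut], B[ut])
  rs <- apply(ords, 1, function(o) cor(A[ut], B[o, o][ut]))
  expect_equal(res$p, mean(rs >= r_obs - 1e-12), tolerance = 1e-12)
  expect_equal(res$r, r_obs, tolerance = 1e-12)
})

test_that("Mantel r agrees with vegan and p is calibrated under the null", {
  skip_if_not_installed("vegan")
  set.seed(37)
  A <- as.matrix(dist(runif(8)))
  B <- as.matrix(dist(runif(8)))
  r_mine <- mantel(A, B, n_perm = 99, seed = 1)$r
  r_vegan <- vegan::mantel(A, B, permutations = 9)$statistic
  expect_equal(r_mine, unname(r_vegan), tolerance = 1e-12)
  # null calibration: p roughly uniform over independent random matrices
  ps <- vapply(1:60, function(i) {
    set.seed(1000 + i)
    a <- as.matrix(dist(runif(6)))
    b <- as.matrix(dist(runif(6)))
    mantel(a, b, n_perm = 39, seed = i)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.72)
  expect_true(all(ps >= 1 / 40))
})

test_that("great-circle distances use the 6371 km haversine sphere", {
  co <- data.frame(site = c("a", "b", "c", "d"),
                   lat = c(0, 0, 0, 10), lon = c(0, 90, 180, 20))
  D <- geo_distances(co)
  expect_equal(D["a", "a"], 0)
  expect_equal(D["a", "b"], 6371 * pi / 2, tolerance = 1e-6)
  expect_equal(D["a", "c"], 6371 * pi, tolerance = 1e-6)
  expect_true(all(D >= 0) && isTRUE(all.equal(D, t(D))))
  expect_error(geo_distances(data.frame(lat = 91, lon = 0)), "range")
})
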