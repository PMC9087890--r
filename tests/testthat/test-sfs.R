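test_that("genotype-derived spectra match a brute-force tally", {
  # 2 diploids per lineage; locus 1: west {0,1}, east {0,0} -> cell (1,0)
  G <- rbind(
    w1 = c(0, 0, 1, 2, 1, 0),
    w2 = c(1, 0, 1, 2, 0, 0),
    e1 = c(0, 0, 0, 1, 2, 0),
    e2 = c(0, 0, 0, 1, 1, 0))
  geno <- genotype_matrix(G, c("PW", "PW", "PE", "PE"),
                          c(PW = "west", PE = "east"))
  x <- jsfs_from_genotypes(geno)
  expect_identical(unname(x$n), c(4L, 4L))
  # locus 1 -> (1,0); locus 2 monomorphic; locus 3 -> (2,0); locus 4 ->
  # (4,2); locus 5 -> (1,3); locus 6 monomorphic
  expect_identical(attr(x, "n_monomorphic"), 2L)
  expect_equal(jsfs_total(x), 4)
  expect_equal(x$counts[2, 1], 1)  # (1,0)
  expect_equal(x$counts[3, 1], 1)  # (2,0)
  expect_equal(x$counts[5, 3], 1)  # (4,2)
  expect_equal(x$counts[2, 4], 1)  # (1,3)

  # independent brute-force tally over a random matrix
  set.seed(42)
  G2 <- matrix(sample(0:2, 8 * 25, replace = TRUE), 8, 25)
  geno2 <- genotype_matrix(G2, rep(c("A", "B"), each = 4),
                           c(A = "west", B = "east"))
  x2 <- jsfs_from_genotypes(geno2)
  tally <- matrix(0, 9, 9)
  for (l in 1:25) {
    i <- sum(G2[1:4, l]); j <- sum(G2[5:8, l])
    if (i + j == 0 || i + j == 16) next
    tally[i + 1, j + 1] <- tally[i + 1, j + 1] + 1
  }
  expect_equal(x2$counts, tally, ignore_attr = TRUE)
  expect_equal(jsfs_total(x2), sum(tally))
})

test_that("grouping errors are caught", {
  G <- matrix(c(0, 1, 2, 1), 2, 2)
  geno <- genotype_matrix(G, c("A", "A"), c(A = "west"))
  expect_error(jsfs_from_genotypes(geno), "two non-admixed lineages")
})

test_that("projection follows the hypergeometric expectation", {
  # sizes (3,2), one site with i=2 derived of 3; project west to 2
  counts <- matrix(0, 4, 3)
  counts[3, 2] <- 1                 # (i=2, j=1)
  x <- jsfs(counts)
  pr <- project_jsfs(x, c(2, 2))
  expect_equal(pr$counts[2, 2], 2 / 3)   # one derived in subsample
  expect_equal(pr$counts[3, 2], 1 / 3)   # both derived
  # identity projection
  expect_equal(project_jsfs(x, c(3, 2))$counts, x$counts)
  expect_error(project_jsfs(x, c(4, 2)), "target")
  # mass fixed-derived after projection is dropped and reported:
  # i=2/3 west and j=2/2 east can project onto the all-derived corner
  counts2 <- matrix(0, 4, 3)
  counts2[3, 3] <- 1
  pr2 <- project_jsfs(jsfs(counts2), c(2, 2))
  expect_equal(jsfs_total(pr2), 2 / 3, tolerance = 1e-12)
  expect_equal(attr(pr2, "mass_lost"), 1 / 3, tolerance = 1e-12)
})

test_that("projection preserves unmasked mass for interior sites", {
  set.seed(3)
  counts <- matrix(rpois(8 * 7, 4), 8, 7)
  counts[1, 1] <- 0; counts[8, 7] <- 0
  x <- jsfs(counts)
  pr <- project_jsfs(x, c(5, 4))
  expect_lte(jsfs_total(pr), jsfs_total(x) + 1e-9)
  expect_equal(jsfs_total(pr) + attr(pr, "mass_lost"), jsfs_total(x),
               tolerance = 1e-12)
})

test_that("folding merges complementary cells and refuses to run twice", {
  # 1-D reduction: n_west = 4, no eastern samples
  counts <- matrix(c(0, 5, 3, 2, 0), 5, 1)
  f <- fold_jsfs(jsfs(counts))
  expect_equal(f$counts[2, 1], 7)   # xi1 + xi3
  expect_equal(f$counts[3, 1], 3)   # xi2 self-paired
  expect_error(fold_jsfs(f), "already folded")
  # total mass conserved on a symmetric spectrum
  set.seed(5)
  m <- matrix(runif(5 * 5), 5, 5)
  sym <- (m + m[5:1, 5:1]) / 2
  sym[1, 1] <- 0; sym[5, 5] <- 0
  x <- jsfs(sym)
  expect_equal(jsfs_total(fold_jsfs(x)), jsfs_total(x), tolerance = 1e-12)
})

test_that("projection commutes with folding on symmetric inputs", {
  set.seed(11)
  m <- matrix(runif(7 * 7), 7, 7)
  sym <- (m + m[7:1, 7:1]) / 2
  sym[1, 1] <- 0; sym[7, 7] <- 0
  x <- jsfs(sym)
  a <- fold_jsfs(project_jsfs(x, c(4, 4)))
  b <- project_jsfs(x, c(4, 4))
  b <- fold_jsfs(b)
  expect_equal(a$counts, b$counts, tolerance = 1e-12)
})

test_that("SFS text dialects round-trip", {
  set.seed(9)
  counts <- matrix(rpois(6 * 5, 3), 6, 5)
  counts[1, 1] <- 0; counts[6, 5] <- 0
  x <- jsfs(counts, n_sites = 123456.5)
  for (d in c("dadi", "obs")) {
    f <- tempfile()
    write_jsfs(x, f, dialect = d)
    y <- read_jsfs(f, dialect = d)
    expect_equal(y$counts, x$counts, tolerance = 1e-12)
    expect_equal(y$n_sites, x$n_sites)
    expect_identical(y$folded, FALSE)
  }
  # folded flag survives the dadi dialect
  xf <- fold_jsfs(x)
  f <- tempfile()
  write_jsfs(xf, f, dialect = "dadi")
  expect_true(read_jsfs(f, "dadi")$folded)
  # malformed header
  writeLines(c("4 4 unfolded", "1 2 3"), f)
  expect_error(read_jsfs(f, "dadi"), "inconsistent|malformed")
  writeLines("nonsense", f)
  expect_error(read_jsfs(f, "obs"), "malformed")
})

test_that("VCF written by the generator reads back to the same dosages", {
  spec <- synthetic_spec(n_loci = 40L, missing_rate = 0.05,
                         pops = data.frame(name = c("W1", "E1"), n = 4L,
                                           lineage = c("west", "east"),
                                           alpha = NA_real_))
  ds <- generate_dataset(spec, seed = 77)
  files <- write_dataset(ds, tempdir(), prefix = "rt")
  geno <- read_vcf_genotypes(files["vcf"], files["popmap"], files["lineages"])
  expect_equal(unname(geno$G[rownames(ds$geno$G), colnames(ds$geno$G)]),
               unname(ds$geno$G))
  expect_identical(unname(geno$popmap[ds$geno$ids]),
                   unname(ds$geno$popmap[ds$geno$ids]))
})
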