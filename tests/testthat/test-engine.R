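test_that("sample configuration needs at least two lineages", {
  expect_error(sample_config(1, 0), "at least 2")
  expect_error(sample_config(0, 1), "at least 2")
  expect_s3_class(sample_config(2, 0), "sample_config")
})

test_that("pairwise coalescence time matches 2N in a single deme", {
  s <- inference_settings(seed = 1)
  N <- 1e4
  m <- build_model("M1", model_params(N_anc = N, N_west = N, N_east = N,
                                      T_div = 1e7), s)
  # n = 2 in the west: total length = 2 * T2, E[T2] = 2N generations
  acc <- accumulate_expected_jsfs(m, sample_config(2, 0), 20000, seed = 5)
  t2 <- acc$mean_total_length / 2
  se <- 2 * N / sqrt(20000)          # sd(T2) = 2N for an exponential
  expect_lt(abs(t2 - 2 * N), 3 * se)
})

test_that("expected total tree length matches 4N * sum(1/i)", {
  s <- inference_settings(seed = 1)
  N <- 1e4; n <- 8
  m <- build_model("M1", model_params(N_anc = N, N_west = N, N_east = N,
                                      T_div = 1e9), s)
  acc <- accumulate_expected_jsfs(m, sample_config(n, 0), 10000, seed = 17)
  expected <- 4 * N * sum(1 / (1:(n - 1)))
  # var(T_tot) = sum (2/(i(i-1)) * 2N * i)^2-ish; bound sd by 4N * 1.3
  se <- 4 * N * 1.3 / sqrt(10000)
  expect_lt(abs(acc$mean_total_length - expected), 3 * se)
})

test_that("panmictic class totals follow the neutral 1/i spectrum (n=4)", {
  s <- inference_settings(seed = 1)
  N <- 1e4
  m <- build_model("M1", model_params(N_anc = N, N_west = N, N_east = N,
                                      T_div = 1e9), s)
  acc <- accumulate_expected_jsfs(m, sample_config(4, 0), 40000, seed = 23)
  xi <- acc$totals[2:4, 1]
  p <- xi / sum(xi)
  expect_equal(p, (1 / (1:3)) / sum(1 / (1:3)), tolerance = 0.02)
})

test_that("identical seeds reproduce identical totals", {
  s <- inference_settings(seed = 1)
  m <- build_model("M6", reference_history(), s)
  a <- accumulate_expected_jsfs(m, sample_config(5, 5), 300, seed = 9)
  b <- accumulate_expected_jsfs(m, sample_config(5, 5), 300, seed = 9)
  expect_identical(a$totals, b$totals)
  d <- accumulate_expected_jsfs(m, sample_config(5, 5), 300, seed = 10)
  expect_false(identical(a$totals, d$totals))
})

test_that("mirror-symmetric histories give transposed spectra", {
  s <- inference_settings(seed = 1)
  p1 <- model_params(N_anc = 2e3, N_west = 5e4, N_east = 2e5, T_div = 1e5,
                     T_contact = 2e4, m_EW = 5e-6, m_WE = 1e-6)
  p2 <- model_params(N_anc = 2e3, N_west = 2e5, N_east = 5e4, T_div = 1e5,
                     T_contact = 2e4, m_EW = 1e-6, m_WE = 5e-6)
  a <- accumulate_expected_jsfs(build_model("M6", p1, s),
                                sample_config(5, 3), 40000, seed = 2)
  b <- accumulate_expected_jsfs(build_model("M6", p2, s),
                                sample_config(3, 5), 40000, seed = 3)
  pa <- a$totals / sum(a$totals)
  pb <- t(b$totals) / sum(b$totals)
  expect_lt(0.5 * sum(abs(pa - pb)), 0.02)
})

test_that("long isolation leaves almost no shared polymorphism", {
  s <- inference_settings(seed = 1)
  p <- model_params(N_anc = 100, N_west = 1e4, N_east = 1e4, T_div = 1e6)
  acc <- accumulate_expected_jsfs(build_model("M1", p, s),
                                  sample_config(4, 4), 5000, seed = 77)
  tot <- acc$totals
  shared <- sum(tot[2:4, 2:4])
  expect_lt(shared / sum(tot), 0.01)
})

test_that("migration adds mass to shared-polymorphism classes", {
  s <- inference_settings(seed = 1)
  base <- list(N_anc = 100, N_west = 1e4, N_east = 1e4, T_div = 1e6,
               T_contact = 5e5)
  shared_mass <- function(m_rate) {
    p <- do.call(model_params, c(base, list(m_EW = m_rate, m_WE = m_rate)))
    acc <- accumulate_expected_jsfs(build_model("M6", p, s),
                                    sample_config(4, 4), 5000, seed = 41)
    sum(acc$totals[2:4, 2:4]) / sum(acc$totals)
  }
  expect_gt(shared_mass(1e-4), shared_mass(0) + 0.01)
})

test_that("single genealogies have consistent branch bookkeeping", {
  s <- inference_settings(seed = 1)
  m <- build_model("M6", reference_history(), s)
  g <- simulate_genealogy(m, sample_config(4, 3), seed = 13)
  br <- g$branches
  expect_equal(sum(br$length), g$total_length)
  expect_true(all(br$i >= 0 & br$i <= 4 & br$j >= 0 & br$j <= 3))
  expect_false(any(br$i == 0 & br$j == 0))
  expect_false(any(br$i == 4 & br$j == 3))   # root excluded
  expect_identical(nrow(br), 2L * 7L - 2L)
  expect_s3_class(g$tree, "phylo")
  expect_true(ape::is.binary(g$tree))
  expect_identical(ape::Ntip(g$tree), 7L)
  f <- tempfile(fileext = ".nwk")
  write_genealogy_newick(g, f)
  reread <- ape::read.tree(f)
  expect_identical(ape::Ntip(reread), 7L)
})

test_that("expected spectra are floored, masked and normalized", {
  s <- inference_settings(seed = 1)
  m <- build_model("M1", toy_params(), s)
  ex <- expected_jsfs(m, sample_config(4, 4), n_sims = 2000, settings = s,
                      seed = 3)
  expect_equal(sum(ex$probs), 1, tolerance = 1e-12)
  expect_identical(ex$probs[1, 1], 0)
  expect_identical(ex$probs[5, 5], 0)
  mask <- matrix(FALSE, 5, 5); mask[1, 1] <- TRUE; mask[5, 5] <- TRUE
  # every admissible cell is supported (floor applied before renormalizing)
  expect_true(all(ex$probs[!mask] >= ex$floor * 0.99))
})
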