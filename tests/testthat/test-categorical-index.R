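test_that("confusion-matrix information and its inverse are mutually
           consistent and match the explicit-matrix oracle", {
  expect_equal(mi_from_p(1, 4), 2)
  expect_equal(mi_from_p(1 / 4, 4), 0)
  expect_equal(mi_from_p(0.7, 9), oracle_mi_matrix(0.7, 9),
               tolerance = 1e-9)
  for (p in c(0.3, 0.5, 0.9)) for (n in c(4, 9, 100)) {
    if (p < 1 / n) next
    expect_lt(abs(p_from_mi(mi_from_p(p, n), n) - p), 1e-6)
  }
  expect_equal(p_from_mi(0, 5), 1 / 5)
  expect_equal(p_from_mi(log2(5), 5), 1)
  expect_warning(p_from_mi(log2(4) + 0.01, 4), "clipped")
  expect_error(mi_from_p(0.1, 4), "1/n")
})

test_that("expected categorical information reduces correctly in the
           degenerate grouping cases and matches the matrix oracle", {
  expect_equal(expected_category_info(1.3, rep(1, 6)), 1.3,
               tolerance = 1e-9)            # singleton categories
  expect_equal(expected_category_info(1.3, 6), 0)  # one category holds all
  expect_equal(expected_category_info(2, c(2, 2)), 1, tolerance = 1e-9)
  # explicit grouped-matrix oracle for an unbalanced case
  mi <- 1.1; sizes <- c(1, 3, 2); n <- 6
  p <- p_from_mi(mi, n)
  J <- matrix((1 - p) / ((n - 1) * n), n, n); diag(J) <- p / n
  idx <- rep(seq_along(sizes), sizes)
  G <- rowsum(t(rowsum(J, idx)), idx)
  ho <- oracle_entropy_pmf(rowSums(G)) + oracle_entropy_pmf(colSums(G)) -
    oracle_entropy_pmf(as.numeric(G))
  expect_equal(expected_category_info(mi, sizes), ho, tolerance = 1e-9)
  # monotone non-decreasing in the stimulus information
  grid <- expected_category_info(seq(0, 2, by = 0.1), c(2, 2))
  expect_true(all(diff(grid) >= -1e-9))
})

test_that("the ceiling caps stimulus information at log2(n_c)", {
  expect_equal(ceiling_category_info(0.4, 9), 0.4)
  expect_equal(ceiling_category_info(4.0, 9), log2(9))
  ci <- info_series(1:4 * 10, c(0.5, 1.5, 3.2, 3.5), rep(0.1, 4))
  out <- ceiling_category_info(ci, 9)
  expect_equal(out, pmin(ci$info, log2(9)))
  expect_true(all(diff(out) >= 0))
})

test_that("the piecewise index interpolates between its references", {
  # CCI exactly at the expected value gives 1; at floor 0; at ceiling 2
  s <- cii_series(cci = c(0.2, 0.5, 0.8, 0.35),
                  floor = rep(0.2, 4), expected = rep(0.5, 4),
                  ceiling = rep(0.8, 4))
  expect_equal(s$cii, c(0, 1, 2, 0.5))
  # degenerate reference spacing makes the index undefined
  sdeg <- cii_series(cci = 0.5, floor = 0.4, expected = 0.4 + 1e-12,
                     ceiling = 0.9)
  expect_true(is.na(sdeg$cii[1]) || sdeg$cii[1] >= 1)
  sdeg2 <- cii_series(cci = 0.3, floor = 0.4, expected = 0.4 + 1e-12,
                      ceiling = 0.9)
  expect_true(is.na(sdeg2$cii[1]))
  # noise outside [0, 2] is clipped but kept raw
  sc <- cii_series(cci = 1.0, floor = 0.2, expected = 0.5, ceiling = 0.9)
  expect_equal(sc$cii[1], 2)
  expect_gt(sc$cii_raw[1], 2)
  expect_identical(attr(sc, "n_clipped"), 1L)
  # inconsistent references (floor > expected) void the lower branch
  sv <- cii_series(cci = 0.45, floor = 0.6, expected = 0.5, ceiling = 0.9)
  expect_true(is.na(sv$cii[1]))
  expect_identical(attr(sv, "n_violated"), 1L)
  # ... but not the ceiling branch, whose references are still ordered
  sv2 <- cii_series(cci = 0.7, floor = 0.6, expected = 0.5, ceiling = 0.9)
  expect_equal(sv2$cii[1], 1.5)
})

test_that("the index reaches its ceiling for category-invariant responses", {
  # within-category identical rates: categorical info equals stimulus info
  spec <- model_neuron("invariant", amplitudes = c(0.01, 0.2),
                       window_ms = 100)
  br <- true_binned_rates(spec)
  mc <- mc_params(chunk = 20000, seed = 41)
  cis <- cumulative_info(br, mc = mc)
  cic <- cumulative_info(br, grouping = spec$categories, mc = mc)
  expd <- expected_category_info(cis$info, c(2, 2))
  ceil <- ceiling_category_info(cis, 2)
  flo <- floor_category_info(br, spec$categories, mc = mc, n_perm = 3)
  s <- cii_series(cic, flo, expd, ceil, time_ms = cis$time_ms)
  # informative bins: where stimulus info is well off zero
  inf_bins <- which(cis$info > 0.5)
  expect_gt(length(inf_bins), 3)
  expect_true(all(s$cii[inf_bins] > 1.9))
  expect_equal(cii_time_average(s, 40, 100), 2, tolerance = 0.1)
})

test_that("the time average uses only defined bins in the window", {
  s <- cii_series(cci = c(0.5, 0.5, 0.5), floor = c(0.2, 0.6, 0.2),
                  expected = c(0.5, 0.5, 0.5), ceiling = c(0.8, 0.8, 0.8),
                  time_ms = c(100, 200, 300))
  expect_equal(cii_time_average(s, 50, 300), 1)   # bin 2 undefined, skipped
  expect_error(cii_time_average(s, 110, 180), "defined")
})
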