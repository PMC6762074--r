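test_that("conditional cumulative entropy is additive and exact", {
  mu <- matrix(0.5, 4, 10)
  br <- binned_rates(mu)
  # identical stimuli, constant rate: t bins of the same Poisson entropy
  expect_equal(conditional_cum_entropy(br, 10), 10 * poisson_entropy(0.5),
               tolerance = 1e-9)
  expect_equal(conditional_cum_entropy(br, 1),
               instantaneous_info(br)$info[1] + poisson_entropy(0.5),
               tolerance = 1e-9)
  set.seed(5)
  mu2 <- matrix(runif(4 * 6, 0.05, 2), 4, 6)
  br2 <- binned_rates(mu2)
  for (t in 2:6) {
    step <- conditional_cum_entropy(br2, t) - conditional_cum_entropy(br2,
                                                                      t - 1)
    expect_equal(step, mean(poisson_entropy(mu2[, t])), tolerance = 1e-12)
  }
})

test_that("Monte Carlo joint entropy agrees with exhaustive enumeration", {
  # a 3-SE band is a statistical statement: allow the expected rare
  # excursion over the 20 random configurations instead of gating each one
  set.seed(77)
  viol <- 0L
  for (k in 1:20) {
    nb <- sample(2:3, 1)
    mu <- matrix(runif(4 * nb, 0.05, 0.35), 4, nb)
    br <- binned_rates(mu, r_max = 5, mass_tol = 1e-4)
    ho <- oracle_enum_joint_entropy(mu, r_max = 5)
    m <- mc_joint_entropy(br, nb, mc_params(chunk = 10000, seed = 100 + k))
    expect_lt(abs(m$h - ho), 0.05)            # always close in absolute terms
    if (abs(m$h - ho) >= 3 * m$se + 1e-3) viol <- viol + 1L
  }
  expect_lte(viol, 2L)
})

test_that("single-bin joint entropy reduces to the marginal mixture", {
  mu <- matrix(c(0.1, 0.4, 0.9, 1.8), 4, 3)
  br <- binned_rates(mu)
  m <- mc_joint_entropy(br, 1, mc_params(chunk = 20000, seed = 3))
  expect_lt(abs(m$h - mixture_entropy(mu[, 1])), 3 * m$se + 1e-3)
})

test_that("identical stimuli factorise: joint entropy is the sum of
           marginals and cumulative information is null", {
  br <- binned_rates(matrix(0.6, 4, 5))
  hsum <- 5 * poisson_entropy(0.6)
  for (ord in 1:3)
    expect_equal(markov_joint_entropy(br, 5, order = ord), hsum,
                 tolerance = 1e-9)
  m <- mc_joint_entropy(br, 5, mc_params(chunk = 20000, seed = 9))
  expect_lt(abs(m$h - hsum), 3 * m$se + 1e-3)
  ci <- cumulative_info(br, mc = mc_params(chunk = 20000, se_stop = 0.005,
                                           max_samples = 200000,
                                           seed = 11))
  expect_true(all(abs(ci$info) < 0.02))
  expect_lte(sum(abs(ci$info) > 3 * ci$se + 1e-3), 1L)
})

test_that("the Markov chain is exact at full order and upper-bounds the
           entropy-derived information at truncated order", {
  set.seed(13)
  mu <- matrix(runif(4 * 3, 0.05, 0.4), 4, 3)
  br <- binned_rates(mu, r_max = 6, mass_tol = 1e-4)
  ho <- oracle_enum_joint_entropy(mu, r_max = 6)
  expect_equal(markov_joint_entropy(br, 3, order = 3), ho,
               tolerance = 1e-9)
  # correlated-in-time distinct rates: order-1 overestimates the entropy
  mu_corr <- matrix(rep(c(0.1, 0.2, 0.3, 0.4), 3), 4, 3)
  brc <- binned_rates(mu_corr, r_max = 6, mass_tol = 1e-4)
  h_exact <- oracle_enum_joint_entropy(mu_corr, r_max = 6)
  expect_gte(markov_joint_entropy(brc, 3, order = 1), h_exact - 1e-12)
  expect_error(markov_joint_entropy(br, 3, order = 3, max_states = 10),
               "budget")
})

test_that("the exact running window reduces to instantaneous information
           at one bin and vanishes for identical stimuli", {
  set.seed(23)
  mu <- matrix(runif(4 * 4, 0.05, 1.5), 4, 4)
  br <- binned_rates(mu, r_max = 15, mass_tol = 1e-9)
  w1 <- exact_window_info(br, n_bins = 1)
  expect_equal(w1$info, instantaneous_info(br)$info, tolerance = 1e-10)
  br0 <- binned_rates(matrix(0.8, 4, 4))
  expect_equal(exact_window_info(br0, n_bins = 2)$info, rep(0, 4),
               tolerance = 1e-10)
})

test_that("estimator ordering: running window <= Monte Carlo <= Markov on a
           correlated synthetic neuron", {
  # slowly varying distinct rates, strong temporal correlation
  tt <- seq_len(8)
  mu <- rbind(0.08 + 0.04 * tt, 0.40 - 0.03 * tt,
              0.20 + 0.02 * tt, 0.30 - 0.01 * tt)
  br <- binned_rates(mu, r_max = 7, mass_tol = 1e-4)
  mc <- mc_params(chunk = 20000, seed = 17)
  ci_mc <- cumulative_info(br, mc = mc)
  wi <- exact_window_info(br, n_bins = 4)
  hcond <- vapply(1:8, function(t) conditional_cum_entropy(br, t), 0)
  ci_mark <- vapply(1:8, function(t)
    markov_joint_entropy(br, t, order = 4), 0) - hcond
  viol <- 0L
  for (t in 5:8) {
    if (wi$info[t] >= ci_mc$info[t] + 3 * ci_mc$se[t]) viol <- viol + 1L
    if (ci_mark[t] <= ci_mc$info[t] - 3 * ci_mc$se[t]) viol <- viol + 1L
    expect_lte(wi$info[t], ci_mark[t] + 6 * ci_mc$se[t])
  }
  expect_lte(viol, 1L)
})

test_that("cumulative information is reproducible, bounded and monotone
           within Monte Carlo error", {
  set.seed(31)
  mu <- matrix(runif(4 * 6, 0.05, 1.2), 4, 6)
  br <- binned_rates(mu)
  mc <- mc_params(chunk = 20000, seed = 19)
  a <- cumulative_info(br, mc = mc)
  b <- cumulative_info(br, mc = mc)
  expect_identical(a, b)                       # seeded determinism
  expect_true(all(a$info <= log2(4) + 3 * a$se))
  expect_true(all(diff(a$info) >= -3 * a$se[-1]))
  # categorical variant bounded by log2(n_c)
  cats <- setNames(c("A", "A", "B", "B"), paste0("S", 1:4))
  brc <- binned_rates(mu, categories = cats)
  ac <- cumulative_info(brc, grouping = cats, mc = mc)
  expect_true(all(ac$info <= log2(2) + 3 * ac$se))
})

test_that("unreliable estimates abort the series at the flagged bin", {
  br <- binned_rates(matrix(c(0.1, 0.5, 1, 2), 4, 6))
  # absurdly strict abort threshold forces the flag immediately
  mc <- mc_params(chunk = 500, se_stop = 1e-9, max_samples = 1000,
                  se_abort = 1e-8, seed = 23)
  ci <- cumulative_info(br, mc = mc)
  expect_identical(attr(ci, "abort_bin"), 1L)
  expect_true(all(is.na(ci$info)))
  expect_error(mc_params(se_stop = 0.7, se_abort = 0.6), "se_stop")
})
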