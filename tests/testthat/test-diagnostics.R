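test_that("the Poisson GOF test keeps its size under the null and rejects
           zero-variance counts", {
  spec <- model_neuron("rate", window_ms = 200)
  fracs <- numeric(10)
  for (s in seq_len(10)) {
    spk <- sample_spikes(spec, 10, seed = 700 + s)
    bc <- bin_counts(spk, 10)
    br <- integrate_to_bins(rate_ensemble(spk, jackknife = FALSE))
    fracs[s] <- poisson_gof(bc, br, n_boot = 200, seed = s)$rejected_fraction
  }
  expect_lte(mean(fracs), 1.5 * 0.05)
  # zero-variance counts at mean 2 are non-Poisson at the cell level
  # (two-tailed p ~ 0.02 at M = 10; BH rejection additionally needs the
  # violation to be widespread, tested below)
  spk <- sample_spikes(spec, 10, seed = 799)
  bc <- bin_counts(spk, 10)
  br <- integrate_to_bins(rate_ensemble(spk, jackknife = FALSE))
  for (id in names(bc$counts)) bc$counts[[id]][, 1] <- 2L
  br$mu[, 1] <- 2
  g <- poisson_gof(bc, br, n_boot = 2000, seed = 5)
  expect_true(all(g$p_values[, 1] < 0.05))
  # a quarter of the cells strongly non-Poisson: BH flags them
  for (id in names(bc$counts)) bc$counts[[id]][, 1:5] <- 4L
  br$mu[, 1:5] <- 4
  g3 <- poisson_gof(bc, br, n_boot = 2000, seed = 7)
  expect_gte(g3$rejected_fraction, 0.2)
  # all-zero cells are excluded, not counted
  bc$counts[[1]][, 6] <- 0L
  g2 <- poisson_gof(bc, br, n_boot = 100, seed = 6)
  expect_true(is.na(g2$p_values[1, 6]))
  expect_gte(g2$n_excluded, 1)
})

test_that("Fano factors match hand computation and center at 1 for Poisson
           counts", {
  x <- spike_train_set(list(
    s = list(category = "C",
             trials = list(numeric(0), numeric(0), c(5), c(7)))),
    window_ms = 10)
  f <- fano_series(bin_counts(x, 10))
  expect_equal(f$fano[1], var(c(0, 0, 1, 1)) / 0.5, tolerance = 1e-12)
  expect_equal(f$fano[1], (1 / 3) / 0.5, tolerance = 1e-12)
  fp <- fano_series(bin_counts(x, 10), var_type = "population")
  expect_equal(fp$fano[1], 0.25 / 0.5, tolerance = 1e-12)
  # identical counts across trials: Fano 0
  y <- spike_train_set(list(
    s = list(category = "C", trials = list(c(1), c(2), c(3)))),
    window_ms = 10)
  expect_equal(fano_series(bin_counts(y, 10))$fano[1], 0)
  # Poisson null: average over many stimuli and seeds near 1, converging
  # with the trial count
  spec <- model_neuron("custom", rates = matrix(0.08, 20, 600))
  f10 <- mean(vapply(1:3, function(s)
    fano_series(bin_counts(sample_spikes(spec, 10, seed = 810 + s)))$mean,
    0))
  f200 <- fano_series(bin_counts(sample_spikes(spec, 200, seed = 820)))$mean
  expect_lt(abs(f10 - 1), 0.1)
  expect_lt(abs(f200 - 1), abs(f10 - 1) + 0.02)
})

test_that("noise correlations vanish for independent Poisson counts and
           appear under shared trial gain", {
  spec <- model_neuron("custom", rates = matrix(0.15, 6, 600))
  vals <- vapply(1:10, function(s)
    noise_correlation(bin_counts(sample_spikes(spec, 10, seed = 830 + s),
                                 10))$mean, 0)
  expect_lt(abs(mean(vals)), 0.02)
  # trial-wise gain shared across bins induces positive noise correlation
  set.seed(88)
  counts <- lapply(1:4, function(i) {
    g <- exp(rnorm(10, 0, 0.6))
    t(vapply(g, function(gj) rpois(20, gj * 1.5), integer(20)))
  })
  names(counts) <- paste0("s", 1:4)
  bc <- structure(list(bin_ms = 10, n_bins = 20L,
                       categories = setNames(paste0("s", 1:4),
                                             paste0("s", 1:4)),
                       counts = counts), class = "binned_counts")
  expect_gt(noise_correlation(bc)$mean, 0.1)
  # a single bin yields no pairs
  one <- structure(list(bin_ms = 10, n_bins = 1L, categories = c(s = "s"),
                        counts = list(s = matrix(rpois(5, 1), 5, 1))),
                   class = "binned_counts")
  expect_length(noise_correlation(one)$values, 0)
})

test_that("stimulus correlations reflect the persistence of tuning", {
  # constant distinct rates: perfectly persistent tuning
  br <- binned_rates(matrix(c(0.1, 0.4, 0.8, 1.2), 4, 10))
  expect_equal(stimulus_correlation(br)$mean, 1, tolerance = 1e-12)
  # independently shuffled rates across bins: near zero on average
  set.seed(91)
  mu <- matrix(runif(8 * 40, 0.05, 2), 8, 40)
  expect_lt(abs(stimulus_correlation(binned_rates(mu))$mean), 0.15)
  # adjacent disjoint bursts, analysed at the burst timescale: the active
  # stimulus changes at every step, so tuning is anti-persistent
  spec <- model_neuron("temporal", amplitudes = 0.1,
                       burst_windows = list(c(0, 150), c(150, 300),
                                            c(300, 450), c(450, 600)),
                       baseline = 0.002)
  brt <- true_binned_rates(spec, bin_ms = 150)
  expect_lt(stimulus_correlation(brt)$mean, 0)
})

test_that("the coherence information rate follows its closed form and the
           band-limited fraction approaches one", {
  fr <- seq(0, 500, by = 1)
  g2 <- ifelse(fr <= 50, 0.5, 0)
  expect_equal(coherence_info(g2, fr, 50), 50, tolerance = 1e-9)
  # full-band integral only picks up the trapezoid sliver at the band edge
  expect_lte(abs(coherence_info(g2, fr, 500) - 50), 0.5 + 1e-9)
  # rate modulated only at 5 Hz: nearly all coherence information < 50 Hz
  rate <- 0.08 + 0.05 * sin(2 * pi * 5 * (1:600) / 1000)
  spec <- model_neuron("custom",
                       rates = matrix(rate, 30, 600, byrow = TRUE))
  spk <- sample_spikes(spec, 20, seed = 95)
  frac <- coherence_info_fraction(spk, n_split = 4, seed = 96)
  expect_gt(as.numeric(frac), 0.95)
  # a silent neuron has no defined fraction
  silent <- sample_spikes(model_neuron("custom",
                                       rates = matrix(0, 2, 600)), 4,
                          seed = 97)
  expect_true(is.na(coherence_info_fraction(silent, seed = 98)))
})

test_that("the cumulative rate-power fraction behaves as a spectral check", {
  expect_equal(power_fraction(matrix(0.05, 1, 600)), 1)
  rate5 <- 0.08 + 0.05 * sin(2 * pi * 5 * (1:600) / 1000)
  expect_gt(power_fraction(matrix(rate5, 1, 600, byrow = TRUE)), 0.99)
  # 100 Hz modulation: only the DC share remains below 50 Hz
  rate100 <- 0.1 + 0.05 * sin(2 * pi * 100 * (1:600) / 1000)
  pf <- power_fraction(matrix(rate100, 1, 600, byrow = TRUE))
  dc_share <- 0.1^2 / (0.1^2 + 0.05^2 / 2)
  expect_lt(abs(pf - dc_share), 0.06)
})
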