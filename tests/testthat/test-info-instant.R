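test_that("closed-form Poisson entropy equals direct pmf summation", {
  # large means need a wider truncation to satisfy the mass guard
  for (mu in c(0.05, 0.5, 1, 2, 5, 8))
    expect_equal(poisson_entropy(mu, r_max = 60),
                 oracle_pois_entropy(mu, r_max = 60), tolerance = 1e-10)
  # vectorised call agrees elementwise
  mus <- c(0.05, 0.5, 2)
  expect_equal(poisson_entropy(mus),
               vapply(mus, oracle_pois_entropy, 0), tolerance = 1e-10)
  expect_error(poisson_entropy(50, r_max = 20), "r_max")
  expect_error(poisson_entropy(-1), "positive")
})

test_that("mixture entropy matches its oracle and Jensen's inequality", {
  expect_equal(mixture_entropy(rep(0.7, 4)), poisson_entropy(0.7),
               tolerance = 1e-12)
  mus <- c(2, 0.05, 0.05, 0.05)
  expect_equal(mixture_entropy(mus), oracle_mixture_entropy(mus),
               tolerance = 1e-10)
  set.seed(8)
  for (k in 1:10) {
    mus <- runif(4, 0.05, 3)
    pr <- runif(4); pr <- pr / sum(pr)
    expect_gte(mixture_entropy(mus, pr, r_max = 30) + 1e-12,
               sum(pr * poisson_entropy(mus, r_max = 30)))
  }
})

test_that("stimulus priors follow the equal-stimulus and equal-category
           schemes", {
  cm <- c(a = "DC", b = "DC", c = "Te", d = "Te")
  expect_equal(unname(stimulus_priors(cm, "equal_stimulus")), rep(0.25, 4))
  expect_equal(unname(stimulus_priors(cm, "equal_category")), rep(0.25, 4))
  cm2 <- c(a = "DC", b = "Te", c = "Te", d = "Te")
  expect_equal(unname(stimulus_priors(cm2, "equal_category")),
               c(1 / 2, 1 / 6, 1 / 6, 1 / 6))
  set.seed(3)
  for (k in 1:10) {
    n <- sample(2:8, 1)
    cm <- setNames(sample(LETTERS[1:3], n, replace = TRUE),
                   paste0("s", 1:n))
    for (sch in c("equal_stimulus", "equal_category"))
      expect_equal(sum(stimulus_priors(cm, sch)), 1, tolerance = 1e-12)
  }
})

test_that("instantaneous information matches direct summation and is zero
           for indistinguishable stimuli", {
  # identical rates: exactly zero at every bin
  br0 <- binned_rates(matrix(0.4, 4, 6))
  expect_equal(instantaneous_info(br0)$info, rep(0, 6), tolerance = 1e-12)
  # the strongly-driven bin: one stimulus at 2 expected counts vs baseline
  mus <- c(2, 0.05, 0.05, 0.05)
  br <- binned_rates(matrix(mus, 4, 1))
  io <- oracle_mixture_entropy(mus) -
    mean(vapply(mus, oracle_pois_entropy, 0))
  expect_equal(instantaneous_info(br)$info[1], io, tolerance = 1e-9)
  expect_equal(io, 0.509, tolerance = 0.01)   # near the 0.5-bit peak
  # random rates: package vs independent direct summation at every bin
  set.seed(19)
  mu <- matrix(runif(4 * 5, 0.05, 2.2), 4, 5)
  bri <- binned_rates(mu)
  ii <- instantaneous_info(bri)$info
  for (b in 1:5) {
    expect_equal(ii[b],
                 oracle_mixture_entropy(mu[, b]) -
                   mean(vapply(mu[, b], oracle_pois_entropy, 0)),
                 tolerance = 1e-9)
  }
  expect_true(all(ii >= 0 & ii <= log2(4)))
})

test_that("categorical information never exceeds stimulus information", {
  set.seed(29)
  for (k in 1:5) {
    mu <- matrix(runif(4 * 6, 0.05, 2), 4, 6)
    cats <- setNames(c("A", "A", "B", "B"), paste0("S", 1:4))
    br <- binned_rates(mu, categories = cats)
    is_ <- instantaneous_info(br)$info
    ic <- instantaneous_info(br, grouping = cats)$info
    expect_true(all(ic <= is_ + 1e-9))
    expect_true(all(ic <= log2(2) + 1e-9))
  }
  br <- binned_rates(matrix(0.5, 4, 2))
  expect_error(instantaneous_info(br, grouping = c(S9 = "A")), "stimuli")
})

test_that("category-averaged conditionals reproduce a hand-built mixture", {
  # two categories of two: p(y|c) is the average member pmf
  mu <- matrix(c(0.1, 0.3, 1.2, 2.0), 4, 1)
  cats <- setNames(c("A", "A", "B", "B"), paste0("S", 1:4))
  br <- binned_rates(mu, categories = cats)
  hA <- oracle_entropy_pmf((dpois(0:20, 0.1) + dpois(0:20, 0.3)) / 2)
  hB <- oracle_entropy_pmf((dpois(0:20, 1.2) + dpois(0:20, 2.0)) / 2)
  hM <- oracle_mixture_entropy(c(0.1, 0.3, 1.2, 2.0))
  expect_equal(instantaneous_info(br, grouping = cats)$info[1],
               hM - (hA + hB) / 2, tolerance = 1e-9)
})
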