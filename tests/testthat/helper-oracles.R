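# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package internals: plain loops
# over truncated count space and stats::dpois only.

oracle_entropy_pmf <- function(p) {
  h <- 0
  for (v in p) if (v > 1e-300) h <- h - v * log2(v)
  h
}

oracle_pois_entropy <- function(mu, r_max = 20) {
  oracle_entropy_pmf(stats::dpois(0:r_max, mu))
}

oracle_mixture_entropy <- function(mus, priors = rep(1 / length(mus),
                                                     length(mus)),
                                   r_max = 20) {
  p <- numeric(r_max + 1)
  for (i in seq_along(mus))
    p <- p + priors[i] * stats::dpois(0:r_max, mus[i])
  oracle_entropy_pmf(p)
}

# exact joint entropy of the stimulus mixture over all count vectors,
# nested-loop enumeration (bins = columns of mu)
oracle_enum_joint_entropy <- function(mu, priors = rep(1 / nrow(mu),
                                                       nrow(mu)),
                                      r_max) {
  nb <- ncol(mu)
  grid <- as.matrix(expand.grid(rep(list(0:r_max), nb)))
  h <- 0
  for (r in seq_len(nrow(grid))) {
    p <- 0
    for (i in seq_len(nrow(mu))) {
      pi <- priors[i]
      for (b in seq_len(nb)) pi <- pi * stats::dpois(grid[r, b], mu[i, b])
      p <- p + pi
    }
    if (p > 1e-300) h <- h - p * log2(p)
  }
  as.numeric(h)
}

# mutual information of the symmetric confusion matrix, built explicitly
oracle_mi_matrix <- function(p, n) {
  J <- matrix((1 - p) / ((n - 1) * n), n, n)
  diag(J) <- p / n
  oracle_entropy_pmf(rowSums(J)) + oracle_entropy_pmf(colSums(J)) -
    oracle_entropy_pmf(as.numeric(J))
}

# small deterministic spike set: 2 stimuli x 3 trials, 100 ms window
tiny_spike_set <- function() {
  spike_train_set(list(
    a = list(category = "C1",
             trials = list(c(5, 12, 90), c(40.5), numeric(0))),
    b = list(category = "C2",
             trials = list(c(0, 99.99), c(33, 34, 35), c(7)))
  ), window_ms = 100, neuron_id = "tiny")
}

# random valid spike set for property tests
random_spike_set <- function(seed, n_stim = 3, window_ms = 200) {
  set.seed(seed)
  sts <- list()
  for (i in seq_len(n_stim)) {
    m <- sample(2:5, 1)
    trials <- lapply(seq_len(m), function(j) {
      k <- rpois(1, 4)
      sort(runif(k, 0, window_ms - 1e-6))
    })
    sts[[paste0("s", i)]] <- list(category = sample(c("X", "Y"), 1),
                                  trials = trials)
  }
  spike_train_set(sts, window_ms = window_ms,
                  neuron_id = paste0("rand", seed))
}
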