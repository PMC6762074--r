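#' Bootstrap goodness-of-fit test of the Poisson assumption
#'
#' For every (stimulus, bin) cell, the observed statistic is the Poisson
#' log-likelihood of the `M` trial counts, each evaluated under the
#' delete-one mean of the other `M-1` trials.  The null distribution is built
#' from `n_boot` simulated sets of `M` draws from a Poisson with the
#' kernel-estimated mean, scored the same way.  Two-tailed p-values use the
#' doubling convention with a `(r+1)/(n_boot+1)` continuity correction and
#' are Benjamini-Hochberg corrected across all cells of the neuron.
#'
#' Cells whose trials are all zero have no usable statistic and are excluded
#' from the rejected fraction.  Zero delete-one means are floored at
#' `0.5/(M-1)` counts so log-likelihoods stay finite.
#'
#' @param counts A [bin_counts()] object.
#' @param rates A `binned_rates` object holding the kernel-estimated means
#'   (same binning).
#' @param n_boot Null samples per cell (default 1000).
#' @param alpha FDR level (default 0.05).
#' @param seed Integer seed.
#' @return List with `p_values` and `p_adjusted` (stimuli x bins matrices),
#'   `rejected_fraction`, `n_cells` and `n_excluded`.
#' @export
poisson_gof <- function(counts, rates, n_boot = 1000, alpha = 0.05, seed) {
  stopifnot(inherits(counts, "binned_counts"), inherits(rates, "binned_rates"))
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  ids <- names(counts$counts)
  nb <- counts$n_bins
  pv <- matrix(NA_real_, length(ids), nb, dimnames = list(ids, NULL))
  ll_deleteone <- function(y) {
    M <- length(y)
    mu_del <- pmax((sum(y) - y) / (M - 1), 0.5 / (M - 1))
    sum(stats::dpois(y, mu_del, log = TRUE))
  }
  for (i in seq_along(ids)) {
    cm <- counts$counts[[ids[i]]]
    M <- nrow(cm)
    for (b in seq_len(nb)) {
      y <- cm[, b]
      if (all(y == 0L)) next                      # degenerate cell
      ll_obs <- ll_deleteone(y)
      mu_kde <- rates$mu[ids[i], b]
      ll_null <- vapply(seq_len(n_boot), function(r)
        ll_deleteone(stats::rpois(M, mu_kde)), 0)
      lo <- (sum(ll_null <= ll_obs) + 1) / (n_boot + 1)
      hi <- (sum(ll_null >= ll_obs) + 1) / (n_boot + 1)
      pv[i, b] <- min(1, 2 * min(lo, hi))
    }
  }
  padj <- matrix(stats::p.adjust(pv, method = "BH"), nrow(pv), ncol(pv),
                 dimnames = dimnames(pv))
  usable <- is.finite(pv)
  list(p_values = pv, p_adjusted = padj,
       rejected_fraction = mean(padj[usable] <= alpha),
       n_cells = sum(usable), n_excluded = sum(!usable))
}

#' Time-varying Fano factor
#'
#' Across-trial variance over mean of the spike count in each bin, computed
#' per stimulus and averaged across stimuli.  Bins where a stimulus has zero
#' mean count are excluded for that stimulus.  A Poisson process has Fano
#' factor 1 at every bin.
#'
#' @param counts A [bin_counts()] object.
#' @param var_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return List with `fano` (per-bin average), `mean` (over bins),
#'   `per_stimulus` (stimuli x bins matrix).
#' @export
fano_series <- function(counts, var_type = c("sample", "population")) {
  stopifnot(inherits(counts, "binned_counts"))
  var_type <- match.arg(var_type)
  per <- vapply(counts$counts, function(cm) {
    M <- nrow(cm)
    mu <- colMeans(cm)
    v <- apply(cm, 2L, stats::var)
    if (var_type == "population") v <- v * (M - 1) / M
    ifelse(mu > 0, v / mu, NA_real_)
  }, numeric(counts$n_bins))
  per <- if (is.matrix(per)) t(per) else matrix(per, ncol = 1L)
  fano <- colMeans(per, na.rm = TRUE)
  list(fano = fano, mean = mean(fano, na.rm = TRUE), per_stimulus = per)
}

#' Noise correlation between successive bins
#'
#' Pearson correlation, across trials of the same stimulus, between the
#' count residuals (count minus the across-trial mean of the bin) of
#' consecutive bins, averaged over bin pairs and stimuli.  Independence of
#' counts between bins given the stimulus — the assumption behind the
#' additive conditional entropy — implies a mean near zero.
#'
#' @param counts A [bin_counts()] object (>= 3 trials per stimulus).
#' @return List with `mean` and `values` (all per-(stimulus, pair)
#'   correlations; zero-variance pairs skipped).
#' @export
noise_correlation <- function(counts) {
  stopifnot(inherits(counts, "binned_counts"))
  vals <- numeric(0)
  for (cm in counts$counts) {
    if (nrow(cm) < 3L) stop("noise correlation requires >= 3 trials")
    if (counts$n_bins < 2L) break
    r <- sweep(cm, 2L, colMeans(cm))
    for (b in seq_len(counts$n_bins - 1L)) {
      a <- r[, b]; z <- r[, b + 1L]
      if (stats::sd(a) == 0 || stats::sd(z) == 0) next
      vals <- c(vals, stats::cor(a, z))
    }
  }
  list(mean = if (length(vals)) mean(vals) else NA_real_, values = vals)
}

#' Stimulus correlation between successive bins
#'
#' Pearson correlation, across stimuli, of the trial-averaged counts in
#' consecutive bins, averaged over bin pairs.  High values mean the response
#' trajectory is strongly stimulus-driven, so the unconditional response
#' distributions of successive bins are far from independent — the reason the
#' joint response entropy cannot be factorised.
#'
#' @param x A [bin_counts()] object or a `binned_rates` object.
#' @return List with `mean` and `values` (per consecutive bin pair).
#' @export
stimulus_correlation <- function(x) {
  m <- if (inherits(x, "binned_counts")) {
    t(vapply(x$counts, colMeans, numeric(x$n_bins)))
  } else if (inherits(x, "binned_rates")) {
    x$mu
  } else stop("'x' must be binned counts or binned rates")
  if (nrow(m) < 2L) stop("at least 2 stimuli are required")
  vals <- numeric(0)
  for (b in seq_len(ncol(m) - 1L)) {
    a <- m[, b]; z <- m[, b + 1L]
    if (stats::sd(a) == 0 || stats::sd(z) == 0) next
    vals <- c(vals, stats::cor(a, z))
  }
  list(mean = if (length(vals)) mean(vals) else NA_real_, values = vals)
}

# Welch averaged periodogram; returns one-sided psd on freq grid fs*k/nfft
.welch_psd <- function(x, fs, win_ms = 200, overlap = 0.5) {
  L <- as.integer(round(win_ms * fs / 1000))
  L <- min(L, length(x))
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  psd <- acc / length(starts)
  nf <- floor(L / 2) + 1L
  list(psd = psd[seq_len(nf)], freq = fs * (seq_len(nf) - 1L) / L)
}

# Welch magnitude-squared coherence of two signals (same segmentation).
# The raw segment-averaged coherence of independent signals has expectation
# ~1/K for K averaged segments; the standard debiasing (K*g2 - 1)/(K - 1)
# removes that floor so broadband noise does not masquerade as coherence.
.welch_cross <- function(x, y, fs, win_ms = 200, overlap = 0.5) {
  L <- as.integer(round(win_ms * fs / 1000))
  L <- min(L, length(x))
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  sxx <- syy <- 0; sxy <- 0 + 0i
  for (s in starts) {
    fx <- stats::fft(x[s:(s + L - 1L)] * w)
    fy <- stats::fft(y[s:(s + L - 1L)] * w)
    sxx <- sxx + Mod(fx)^2
    syy <- syy + Mod(fy)^2
    sxy <- sxy + fx * Conj(fy)
  }
  nf <- floor(L / 2) + 1L
  g2 <- Mod(sxy)^2 / (sxx * syy)
  K <- length(starts)
  if (K > 1L) g2 <- (K * g2 - 1) / (K - 1)
  list(gamma2 = pmin(pmax(g2[seq_len(nf)], 0), 1 - 1e-12),
       freq = fs * (seq_len(nf) - 1L) / L, n_segments = K)
}

#' Information rate from a coherence curve
#'
#' Integrates `-log2(1 - gamma2)` over frequency up to `f_lim` (trapezoid
#' rule), the channel-capacity style information rate in bits/s implied by a
#' magnitude-squared coherence between response and mean response.
#'
#' @param gamma2 Coherence values in `[0, 1)`.
#' @param freq Matching frequencies (Hz).
#' @param f_lim Upper integration limit (Hz).
#' @return Information rate in bits/s.
#' @export
coherence_info <- function(gamma2, freq, f_lim = max(freq)) {
  stopifnot(length(gamma2) == length(freq))
  sel <- freq <= f_lim + 1e-9
  f <- freq[sel]
  v <- -log2(1 - pmin(pmax(gamma2[sel], 0), 1 - 1e-12))
  if (length(f) < 2L) return(0)
  sum(diff(f) * (v[-1L] + v[-length(v)]) / 2)
}

#' Fraction of coherence information below a cutoff frequency
#'
#' Splits the trials of every stimulus into random halves, builds the two
#' half PSTHs (concatenated across stimuli), estimates their Welch coherence
#' (200 ms Hann windows, 50% overlap), corrects it to the coherence between a
#' single trial and the true mean rate, and integrates the implied
#' information rate.  Returned is the ratio of the rate integrated up to
#' `f_cut` to the rate up to `f_max`, averaged over `n_split` random
#' halvings — the fraction of response dynamics retained when rates are
#' sampled at `2*f_cut` Hz.
#'
#' The correction from the split-half coherence `g2` with `M` total trials is
#' `1 / (1 + (M/2) * (sqrt(1/g2) - 1))`, the standard relation for
#' trial-averaged responses with independent noise.
#'
#' @param x A [spike_train_set()].
#' @param f_cut Cutoff frequency (Hz, default 50).
#' @param f_max Full-band limit (Hz, default 500).
#' @param n_split Random halvings to average (default 10).
#' @param seed Integer seed.
#' @param fs PSTH sampling rate (Hz, default 1000).
#' @return Fraction in `[0, 1]` (`NA` for a silent neuron), with attribute
#'   `info_rate_full` (bits/s up to `f_max`).
#' @export
coherence_info_fraction <- function(x, f_cut = 50, f_max = 500, n_split = 10,
                                    seed, fs = 1000) {
  stopifnot(inherits(x, "spike_train_set"))
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  M <- min(n_trials(x))
  if (M < 4L) stop("coherence requires at least 4 trials per stimulus")
  if (sum(vapply(x$stimuli, function(s) sum(lengths(s$trials)), 0L)) == 0L)
    return(structure(NA_real_, info_rate_full = 0))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  nt <- as.integer(round(x$window_ms * fs / 1000))
  psth <- function(trials) {
    h <- 0
    for (tt in trials)
      h <- h + tabulate(pmin(floor(tt * fs / 1000), nt - 1L) + 1L, nbins = nt)
    h * fs / length(trials)                       # spikes/s
  }
  half <- floor(M / 2)
  g2_acc <- 0
  freq <- NULL
  for (k in seq_len(n_split)) {
    p1 <- p2 <- numeric(0)
    for (st in x$stimuli) {
      idx <- sample.int(length(st$trials))
      p1 <- c(p1, psth(st$trials[idx[seq_len(half)]]))
      p2 <- c(p2, psth(st$trials[idx[(half + 1L):(2L * half)]]))
    }
    cs <- .welch_cross(p1, p2, fs)
    g2_acc <- g2_acc + cs$gamma2
    freq <- cs$freq
  }
  # average the split-half coherence over halvings before the trial-count
  # correction: the correction is strongly nonlinear near zero, so noise
  # must be beaten down first
  g2 <- g2_acc / n_split
  # noise-floor gate: the null distribution of the raw segment-averaged
  # coherence is approximately P(g2 > x) = (1-x)^(K-1); frequencies whose
  # (debiased) coherence cannot be told from zero at the 5% level are set
  # to zero, otherwise their rectified noise integrates to a spurious
  # broadband information rate
  K <- cs$n_segments
  thr <- (K * (1 - 0.05^(1 / (K - 1))) - 1) / (K - 1)
  g2[g2 < thr] <- 0
  g2 <- pmax(g2, 1e-12)
  gar <- 1 / (1 + (M / 2) * (sqrt(1 / g2) - 1))
  gar <- pmin(pmax(gar, 0), 1 - 1e-12)
  full <- coherence_info(gar, freq, f_max)
  frac <- if (full > 0) coherence_info(gar, freq, f_cut) / full else NA_real_
  structure(frac, info_rate_full = full)
}

#' Fraction of rate power below a cutoff frequency
#'
#' Welch averaged periodogram (200 ms Hann windows, 50% overlap, rate
#' sampled at `fs`) of each stimulus's estimated rate; the cumulative power
#' across frequencies is normalised by the total and evaluated at `f_cut`,
#' then averaged over stimuli.
#'
#' @param rates A `rate_ensemble` (or a numeric matrix of rate curves,
#'   stimuli in rows, sampled at `fs`).
#' @param f_cut Cutoff frequency (Hz, default 50).
#' @param fs Sampling rate (Hz, default taken from the ensemble).
#' @return Fraction in `[0, 1]`.
#' @export
power_fraction <- function(rates, f_cut = 50, fs = NULL) {
  if (inherits(rates, "rate_ensemble")) {
    if (is.null(fs)) fs <- rates$fs
    m <- rates$rate
  } else {
    m <- as.matrix(rates)
    if (is.null(fs)) fs <- 1000
  }
  fr <- apply(m, 1L, function(r) {
    ps <- .welch_psd(r, fs)
    cum <- cumsum(ps$psd) / sum(ps$psd)
    cum[max(which(ps$freq <= f_cut + 1e-9))]
  })
  mean(fr)
}
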