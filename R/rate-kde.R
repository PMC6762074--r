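#' Adaptive kernel estimate of a time-varying firing rate
#'
#' Estimates the trial-averaged firing rate from the pooled spike times of
#' repeated trials with Gaussian kernels.  The bandwidth is first optimised
#' globally by minimising an unbiased estimate of the mean integrated squared
#' error for a Poisson point process, then adapted locally by re-optimising in
#' overlapping windows and interpolating the resulting bandwidth along the
#' sample grid.  Kernels are renormalised over the response window so that
#' mass is not lost at the edges.
#'
#' If fewer than two spikes are available in total, the rate is a constant:
#' `1/(2*M*N)` spikes per sample for zero spikes and `1/(M*N)` for one spike,
#' where `M` is the trial count and `N` the number of rate samples.  The
#' returned rate is floored at the zero-spike constant everywhere so that
#' Poisson log-likelihoods stay finite.
#'
#' @param trials List of numeric spike-time vectors (ms), one per trial
#'   (>= 2 trials).
#' @param window_ms Response window (ms).
#' @param fs Rate sampling frequency (Hz, default 1000).
#' @return Numeric vector of length `window_ms*fs/1000`: rate in spikes/ms at
#'   the sample centers, with attributes `degenerate` (logical) and
#'   `bandwidth_ms` (per-sample bandwidths, `NA` when degenerate).
#' @export
estimate_rate <- function(trials, window_ms = 600, fs = 1000) {
  if (!is.list(trials) || length(trials) < 2L)
    stop("at least 2 trials are required")
  M <- length(trials)
  nt <- as.integer(round(window_ms * fs / 1000))
  dt <- window_ms / nt
  times <- sort(unlist(trials, use.names = FALSE))
  lo <- 1 / (2 * M * nt) / dt                     # spikes/ms fallback floor
  if (length(times) <= 1L) {
    val <- if (length(times) == 0L) lo else 2 * lo
    return(structure(rep(val, nt), degenerate = TRUE,
                     bandwidth_ms = rep(NA_real_, nt)))
  }
  grid <- (seq_len(nt) - 0.5) * dt
  h <- tabulate(pmin(floor(times / dt), nt - 1L) + 1L, nbins = nt)
  ws <- exp(seq(log(2 * dt), log(window_ms / 4), length.out = 40L))
  cc <- .count_autocorr(h)
  w0 <- ws[which.min(vapply(ws, function(w) .kde_cost(cc, sum(h), w, dt), 0))]
  wloc <- .local_bandwidths(h, grid, dt, w0, ws, window_ms)
  rate <- .kde_eval(h, grid, wloc, M, window_ms)
  structure(pmax(rate, lo), degenerate = FALSE, bandwidth_ms = wloc)
}

# autocorrelation of binned counts, lags 0..n-1 (zero-padded FFT)
.count_autocorr <- function(h) {
  n <- length(h)
  a <- stats::fft(c(h, numeric(n)))
  full <- Re(stats::fft(a * Conj(a), inverse = TRUE)) / (2L * n)
  full[seq_len(n)]
}

# MISE cost for bandwidth w: sum_{ij} phi_{sqrt2 w}(dij) - 2 sum_{i!=j} phi_w(dij)
# evaluated on binned pair counts cc (lags in units of dt)
.kde_cost <- function(cc, n_spikes, w, dt) {
  lags <- (seq_along(cc) - 1L) * dt
  s <- function(sd) {
    k <- stats::dnorm(lags, 0, sd)
    cc[1L] * k[1L] + 2 * sum(cc[-1L] * k[-1L])
  }
  s(sqrt(2) * w) - 2 * (s(w) - n_spikes * stats::dnorm(0, 0, w))
}

# re-optimise the bandwidth in overlapping windows (length 5*w0, 50% overlap)
# and interpolate linearly over the sample grid
.local_bandwidths <- function(h, grid, dt, w0, ws, window_ms) {
  L <- min(5 * w0, window_ms)
  step <- L / 2
  centers <- seq(L / 2, window_ms - L / 2, by = step)
  if (length(centers) < 2L) return(rep(w0, length(grid)))
  wloc <- vapply(centers, function(ctr) {
    sel <- abs(grid - ctr) <= L / 2
    hl <- h
    hl[!sel] <- 0L
    n <- sum(hl)
    if (n < 2L) return(w0)
    cc <- .count_autocorr(hl)
    wgrid <- ws[ws <= L / 2]
    if (length(wgrid) < 2L) wgrid <- ws
    wgrid[which.min(vapply(wgrid, function(w) .kde_cost(cc, n, w, dt), 0))]
  }, 0)
  stats::approx(centers, wloc, xout = grid, rule = 2)$y
}

# evaluate the rate with per-sample bandwidths and edge renormalisation
.kde_eval <- function(h, grid, w, M, window_ms) {
  nz <- which(h > 0L)
  d <- outer(grid, grid[nz], "-")
  K <- exp(-(d / w)^2 / 2) / (w * sqrt(2 * pi))   # w recycles along rows
  z <- stats::pnorm((window_ms - grid) / w) - stats::pnorm(-grid / w)
  as.numeric(K %*% h[nz]) / (M * z)
}

#' Delete-one jackknife replicates of the rate estimate
#'
#' Re-estimates the rate on each of the `M` possible sets of `M-1` trials.
#' By default the per-sample bandwidth profile of the full-sample estimate is
#' reused for every replicate, so that the delete-one estimates are a smooth
#' functional of the retained spikes and the jackknife bias correction built
#' on them cancels the leading `1/M` bias cleanly; with
#' `reuse_bandwidth = FALSE` the bandwidth optimisation is re-run per
#' replicate.
#'
#' @inheritParams estimate_rate
#' @param reuse_bandwidth Reuse the full-sample bandwidth profile
#'   (default `TRUE`).
#' @return A matrix with `M` rows (one delete-one rate curve per row).
#' @export
jackknife_rates <- function(trials, window_ms = 600, fs = 1000,
                            reuse_bandwidth = TRUE) {
  M <- length(trials)
  if (M < 2L) stop("at least 2 trials are required")
  nt <- as.integer(round(window_ms * fs / 1000))
  bw <- NULL
  if (reuse_bandwidth) {
    full <- estimate_rate(trials, window_ms, fs)
    if (!attr(full, "degenerate")) bw <- attr(full, "bandwidth_ms")
  }
  t(vapply(seq_len(M), function(j) {
    as.numeric(.estimate_rate_bw(trials[-j], window_ms, fs, bw))
  }, numeric(nt)))
}

# estimate_rate with an optional fixed bandwidth profile
.estimate_rate_bw <- function(trials, window_ms, fs, bw = NULL) {
  if (is.null(bw)) return(estimate_rate(trials, window_ms, fs))
  M <- length(trials)
  nt <- as.integer(round(window_ms * fs / 1000))
  dt <- window_ms / nt
  times <- sort(unlist(trials, use.names = FALSE))
  lo <- 1 / (2 * M * nt) / dt
  if (length(times) <= 1L) {
    val <- if (length(times) == 0L) lo else 2 * lo
    return(structure(rep(val, nt), degenerate = TRUE,
                     bandwidth_ms = rep(NA_real_, nt)))
  }
  grid <- (seq_len(nt) - 0.5) * dt
  h <- tabulate(pmin(floor(times / dt), nt - 1L) + 1L, nbins = nt)
  rate <- .kde_eval(h, grid, bw, M, window_ms)
  structure(pmax(rate, lo), degenerate = FALSE, bandwidth_ms = bw)
}

#' Estimate rates for all stimuli of a spike train set
#'
#' Convenience wrapper running [estimate_rate()] (and optionally
#' [jackknife_rates()]) for every stimulus.
#'
#' @param x A [spike_train_set()].
#' @param fs Rate sampling frequency (Hz).
#' @param jackknife Logical: also compute delete-one replicates?
#' @return A `rate_ensemble`: list with `rate` (stimuli x samples matrix,
#'   spikes/ms), `jackknife` (list of per-stimulus replicate matrices or
#'   `NULL`), `degenerate` (logical per stimulus), `fs`, `window_ms`,
#'   `categories` and `n_trials`.
#' @export
rate_ensemble <- function(x, fs = 1000, jackknife = TRUE) {
  stopifnot(inherits(x, "spike_train_set"))
  nt <- as.integer(round(x$window_ms * fs / 1000))
  ids <- names(x$stimuli)
  rate <- matrix(NA_real_, length(ids), nt, dimnames = list(ids, NULL))
  deg <- logical(length(ids))
  jk <- if (jackknife) stats::setNames(vector("list", length(ids)), ids)
        else NULL
  for (i in seq_along(ids)) {
    est <- estimate_rate(x$stimuli[[i]]$trials, x$window_ms, fs)
    rate[i, ] <- as.numeric(est)
    deg[i] <- attr(est, "degenerate")
    if (jackknife)
      jk[[i]] <- jackknife_rates(x$stimuli[[i]]$trials, x$window_ms, fs)
  }
  structure(list(rate = rate, jackknife = jk, degenerate = deg, fs = fs,
                 window_ms = x$window_ms, categories = category_map(x),
                 n_trials = n_trials(x)),
            class = "rate_ensemble")
}

#' Construct per-bin expected spike counts directly
#'
#' Builds the `binned_rates` container from a matrix of expected counts.
#' Normally produced by [integrate_to_bins()] or [true_binned_rates()]; the
#' direct constructor is useful for analytic test cases.
#'
#' @param mu Numeric matrix of expected counts, stimuli in rows, analysis
#'   bins in columns.  Row names are the stimulus ids.
#' @param bin_ms Bin width (ms).
#' @param r_max Count truncation for entropy sums (default 20).
#' @param categories Named character vector mapping stimulus id to category
#'   (default: every stimulus its own category).
#' @param mass_tol Maximum tolerated Poisson mass beyond `r_max`
#'   (default 1e-12); exceeded mass raises an error asking for a larger
#'   `r_max`.
#' @return A `binned_rates` object.
#' @export
binned_rates <- function(mu, bin_ms = 10, r_max = 20,
                         categories = NULL, mass_tol = 1e-12) {
  mu <- as.matrix(mu)
  if (is.null(rownames(mu))) rownames(mu) <- paste0("S", seq_len(nrow(mu)))
  if (is.null(categories))
    categories <- stats::setNames(rownames(mu), rownames(mu))
  .binned_rates(mu, bin_ms, r_max, categories, mass_tol = mass_tol)
}

# smallest truncation count (at least r_max) keeping the tail mass of a
# Poisson with the given maximum mean below mass_tol — the "raise r_max"
# rule for hot estimated rates
.required_rmax <- function(maxmu, r_max, mass_tol) {
  r <- max(r_max, stats::qpois(mass_tol, maxmu, lower.tail = FALSE))
  while (1 - stats::ppois(r, maxmu) > mass_tol) r <- r + 1L
  as.integer(r)
}

# internal constructor for per-bin expected counts
.binned_rates <- function(mu, bin_ms, r_max, categories, jackknife = NULL,
                          degenerate = NULL, mass_tol = 1e-12) {
  if (any(!is.finite(mu))) stop("expected counts must be finite")
  if (any(mu <= 0)) stop("expected counts must be positive")
  deficit <- 1 - stats::ppois(r_max, max(mu))
  if (deficit > mass_tol)
    stop("truncated Poisson mass deficit ", signif(deficit, 3), " for mu = ",
         signif(max(mu), 4), "; raise r_max above ", r_max)
  structure(list(mu = mu, bin_ms = bin_ms, r_max = as.integer(r_max),
                 categories = categories, jackknife = jackknife,
                 degenerate = degenerate, mass_tol = mass_tol),
            class = "binned_rates")
}

#' @export
print.binned_rates <- function(x, ...) {
  cat("binned_rates: ", nrow(x$mu), " stimuli x ", ncol(x$mu), " bins of ",
      x$bin_ms, " ms (r_max ", x$r_max, ")\n", sep = "")
  cat("  expected counts in [", signif(min(x$mu), 3), ", ",
      signif(max(x$mu), 3), "]",
      if (!is.null(x$jackknife)) "; jackknife replicates attached", "\n",
      sep = "")
  invisible(x)
}

#' Integrate rate curves into per-bin Poisson means
#'
#' Sums the rate samples falling in each analysis bin to obtain the expected
#' spike count per bin, the Poisson parameter driving all information
#' computations, and enforces a lower bound on it (default 1/20 expected
#' counts per bin).  Jackknife replicates, when present, are integrated
#' identically.
#'
#' @param rates A `rate_ensemble` from [rate_ensemble()].
#' @param bin_ms Analysis bin width (ms); must divide the window.
#' @param r_max Count truncation for entropy sums (default 20); raised
#'   automatically when the estimated rates leave more than `mass_tol`
#'   Poisson mass beyond it.
#' @param mu_floor Lower bound on the expected count per bin (default 1/20).
#' @param mass_tol Maximum tolerated Poisson mass beyond `r_max`
#'   (default 1e-12).
#' @return A `binned_rates` object with `mu` (stimuli x bins), optional
#'   `jackknife` replicates, `bin_ms`, `r_max` and `categories`.
#' @export
integrate_to_bins <- function(rates, bin_ms = 10, r_max = 20,
                              mu_floor = 1 / 20, mass_tol = 1e-12) {
  stopifnot(inherits(rates, "rate_ensemble"))
  nb <- rates$window_ms / bin_ms
  if (abs(nb - round(nb)) > 1e-9) stop("'bin_ms' must divide the window")
  nb <- as.integer(round(nb))
  nt <- ncol(rates$rate)
  dt <- rates$window_ms / nt
  grp <- rep(seq_len(nb), each = as.integer(round(nt / nb)))
  integ <- function(m) {
    out <- t(apply(m * dt, 1L, function(r) tapply(r, grp, sum)))
    pmax(out, mu_floor)
  }
  mu <- integ(rates$rate)
  jk <- if (!is.null(rates$jackknife)) lapply(rates$jackknife, integ) else NULL
  maxmu <- max(mu, if (!is.null(jk)) vapply(jk, max, 0) else 0)
  r_max <- .required_rmax(maxmu, r_max, mass_tol)
  .binned_rates(mu, bin_ms = bin_ms, r_max = r_max,
                categories = rates$categories, jackknife = jk,
                degenerate = rates$degenerate, mass_tol = mass_tol)
}

#' Rate-recovery error of the kernel estimator on a model neuron
#'
#' Samples spike trains from a model neuron, re-estimates the rates, and
#' returns the mean absolute deviation between estimated and true rates over
#' all stimuli and time samples (spikes/ms).
#'
#' @param spec A [model_neuron()] specification.
#' @param n_trials Trials per stimulus.
#' @param seed Integer seed for the spike sampling.
#' @return Scalar mean absolute rate error in spikes/ms, with attribute
#'   `per_stimulus` holding the per-stimulus errors.
#' @export
kde_validation_error <- function(spec, n_trials = 10, seed) {
  stopifnot(inherits(spec, "model_neuron_spec"))
  spk <- sample_spikes(spec, n_trials = n_trials, seed = seed)
  ens <- rate_ensemble(spk, fs = spec$fs, jackknife = FALSE)
  err <- abs(ens$rate - spec$rates)
  structure(mean(err), per_stimulus = rowMeans(err))
}
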