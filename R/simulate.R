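#' Model neurons with known time-varying rates
#'
#' Constructs ground-truth inhomogeneous-Poisson model neurons used to
#' validate the information estimators.  Three archetypes encode four stimuli
#' with different neural codes: `"rate"` (constant rates of distinct
#' amplitude), `"onset"` (identical bursts at distinct latencies) and
#' `"temporal"` (identical bursts at distinct, non-overlapping times).  Two
#' further archetypes probe categorical coding: `"invariant"` (stimuli within
#' a category share an identical rate, categories differ strongly) and
#' `"interleaved"` (distinct constant rates whose rank order interleaves the
#' category labels, so labels carry no extra information beyond stimulus
#' identity).
#'
#' @param archetype One of `"rate"`, `"onset"`, `"temporal"`, `"invariant"`,
#'   `"interleaved"`, `"custom"`.
#' @param window_ms Response window (ms).
#' @param fs Rate sampling frequency in Hz (default 1000, i.e. 1 ms steps).
#' @param amplitudes Stimulus amplitudes in spikes/ms.  Meaning depends on the
#'   archetype: constant rates (`rate`, `interleaved`), burst height (`onset`,
#'   `temporal`), or one constant rate per *category* (`invariant`).
#' @param latencies_ms Burst onset latencies for `onset` (one per stimulus).
#' @param duration_ms Burst duration for `onset`.
#' @param burst_windows For `temporal`: a list of `c(start, end)` ms pairs,
#'   one per stimulus; supports must not overlap.
#' @param baseline Baseline rate in spikes/ms added outside bursts.
#' @param n_stim,n_cat Number of stimuli and categories for `invariant`.
#' @param rates For `archetype = "custom"`: a numeric matrix, stimuli in rows,
#'   one column per rate sample.
#' @param categories Optional character vector of category labels, one per
#'   stimulus (defaults depend on the archetype).
#'
#' @return A `model_neuron_spec`: list with `rates` (stimuli x samples matrix,
#'   spikes/ms), `fs`, `window_ms`, `categories` and `archetype`.
#' @export
model_neuron <- function(archetype = c("rate", "onset", "temporal",
                                       "invariant", "interleaved", "custom"),
                         window_ms = 600, fs = 1000,
                         amplitudes = NULL, latencies_ms = c(0, 100, 200, 300),
                         duration_ms = 200, burst_windows = NULL,
                         baseline = 0, n_stim = 4, n_cat = 2,
                         rates = NULL, categories = NULL) {
  archetype <- match.arg(archetype)
  nt <- as.integer(round(window_ms * fs / 1000))
  tt <- (seq_len(nt) - 0.5) * (window_ms / nt)   # sample centers, ms
  mk <- function(n) matrix(baseline, n, nt)
  if (archetype == "rate") {
    if (is.null(amplitudes)) amplitudes <- c(0.01, 0.03, 0.06, 0.09)
    if (any(amplitudes <= 0)) stop("amplitudes must be positive")
    r <- matrix(rep(amplitudes, nt), length(amplitudes), nt)
  } else if (archetype == "onset") {
    if (is.null(amplitudes)) amplitudes <- 0.2
    if (any(amplitudes <= 0)) stop("amplitudes must be positive")
    amplitudes <- rep_len(amplitudes, length(latencies_ms))
    r <- mk(length(latencies_ms))
    for (i in seq_along(latencies_ms)) {
      on <- tt >= latencies_ms[i] & tt < latencies_ms[i] + duration_ms
      r[i, on] <- r[i, on] + amplitudes[i]
    }
  } else if (archetype == "temporal") {
    if (is.null(burst_windows))
      burst_windows <- list(c(50, 150), c(200, 300), c(350, 450), c(500, 600))
    if (is.null(amplitudes)) amplitudes <- 0.1
    if (any(amplitudes <= 0)) stop("amplitudes must be positive")
    amplitudes <- rep_len(amplitudes, length(burst_windows))
    w <- do.call(rbind, burst_windows)
    o <- order(w[, 1L])
    if (any(w[o, 1L][-1L] < w[o, 2L][-nrow(w)]))
      stop("temporal archetype requires non-overlapping burst windows")
    r <- mk(length(burst_windows))
    for (i in seq_along(burst_windows)) {
      on <- tt >= w[i, 1L] & tt < w[i, 2L]
      r[i, on] <- r[i, on] + amplitudes[i]
    }
  } else if (archetype == "invariant") {
    if (is.null(amplitudes)) amplitudes <- c(0.01, 0.2)
    if (any(amplitudes <= 0)) stop("amplitudes must be positive")
    amplitudes <- rep_len(amplitudes, n_cat)
    if (n_stim %% n_cat != 0)
      stop("'invariant' archetype requires n_cat to divide n_stim")
    per <- n_stim / n_cat
    r <- matrix(rep(rep(amplitudes, each = per), nt), n_stim, nt)
    if (is.null(categories))
      categories <- rep(paste0("C", seq_len(n_cat)), each = per)
  } else if (archetype == "interleaved") {
    if (is.null(amplitudes)) amplitudes <- c(0.01, 0.04, 0.08, 0.12)
    if (any(amplitudes <= 0)) stop("amplitudes must be positive")
    r <- matrix(rep(amplitudes, nt), length(amplitudes), nt)
    if (is.null(categories))
      categories <- rep(paste0("C", 1:2), length.out = length(amplitudes))
  } else {                                        # custom
    if (is.null(rates)) stop("'custom' archetype requires a 'rates' matrix")
    r <- as.matrix(rates)
    if (ncol(r) != nt) stop("'rates' must have ", nt, " columns")
  }
  if (any(!is.finite(r)) || any(r < 0)) stop("rates must be finite and >= 0")
  n <- nrow(r)
  rownames(r) <- paste0("S", seq_len(n))
  if (is.null(categories)) categories <- rownames(r)
  categories <- stats::setNames(as.character(rep_len(categories, n)),
                                rownames(r))
  structure(list(rates = r, fs = fs, window_ms = window_ms,
                 categories = categories, archetype = archetype),
            class = "model_neuron_spec")
}

#' @export
print.model_neuron_spec <- function(x, ...) {
  cat("model_neuron_spec '", x$archetype, "': ", nrow(x$rates),
      " stimuli, ", x$window_ms, " ms at ", x$fs, " Hz\n", sep = "")
  cat("  peak rate ", signif(max(x$rates), 3), " spikes/ms; categories: ",
      paste(unique(x$categories), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Sample inhomogeneous-Poisson spike trains from a model neuron
#'
#' Each trial is drawn independently: the spike count in every rate sample
#' interval is Poisson with mean equal to the integral of the rate over the
#' interval, and spike times are uniform within the interval.  This is exact
#' for the piecewise-constant rates produced by [model_neuron()].
#'
#' @param spec A `model_neuron_spec`.
#' @param n_trials Trials per stimulus (>= 2).
#' @param seed Integer seed; the same seed reproduces the same spike set.
#' @return A [spike_train_set()].
#' @export
sample_spikes <- function(spec, n_trials = 10, seed) {
  stopifnot(inherits(spec, "model_neuron_spec"), n_trials >= 2)
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  dt <- spec$window_ms / ncol(spec$rates)       # ms per sample
  edges <- (seq_len(ncol(spec$rates)) - 1L) * dt
  stimuli <- list()
  for (i in seq_len(nrow(spec$rates))) {
    lam <- spec$rates[i, ] * dt                 # expected count per sample
    trials <- vector("list", n_trials)
    for (j in seq_len(n_trials)) {
      k <- stats::rpois(length(lam), lam)
      nz <- which(k > 0L)
      if (length(nz)) {
        tt <- rep(edges[nz], k[nz]) + stats::runif(sum(k[nz]), 0, dt)
        trials[[j]] <- sort(pmin(tt, spec$window_ms * (1 - 1e-12)))
      } else trials[[j]] <- numeric(0)
    }
    stimuli[[rownames(spec$rates)[i]]] <-
      list(category = unname(spec$categories[i]), trials = trials)
  }
  spike_train_set(stimuli, window_ms = spec$window_ms,
                  neuron_id = paste0("model_", spec$archetype))
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Integrate true model rates into per-bin Poisson means
#'
#' Bypasses rate estimation: converts the known rates of a model neuron into
#' the per-bin expected counts used by the information estimators.  The same
#' lower bound on the expected count is enforced as for estimated rates.
#'
#' @param spec A `model_neuron_spec`.
#' @param bin_ms Analysis bin width (ms); must divide the window.
#' @param r_max Count truncation for entropy sums (default 20).
#' @param mu_floor Lower bound on expected counts per bin (default 1/20).
#' @return A `binned_rates` object (see [integrate_to_bins()]).
#' @export
true_binned_rates <- function(spec, bin_ms = 10, r_max = 20, mu_floor = 1 / 20) {
  stopifnot(inherits(spec, "model_neuron_spec"))
  dt <- spec$window_ms / ncol(spec$rates)
  nb <- spec$window_ms / bin_ms
  if (abs(nb - round(nb)) > 1e-9) stop("'bin_ms' must divide the window")
  nb <- as.integer(round(nb))
  per <- ncol(spec$rates) / nb
  if (abs(per - round(per)) > 1e-9)
    stop("'bin_ms' must be a multiple of the rate sampling step")
  grp <- rep(seq_len(nb), each = as.integer(round(per)))
  mu <- t(apply(spec$rates * dt, 1L, function(r) tapply(r, grp, sum)))
  mu <- pmax(mu, mu_floor)
  r_max <- .required_rmax(max(mu), r_max, 1e-12)
  .binned_rates(mu, bin_ms = bin_ms, r_max = r_max,
                categories = spec$categories, jackknife = NULL,
                degenerate = rep(FALSE, nrow(mu)))
}
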