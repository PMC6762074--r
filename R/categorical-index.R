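#' Mutual information of a symmetric confusion matrix
#'
#' For a decoder of `n` equally probable alternatives with correct-decoding
#' probability `p` (the same for every alternative) and errors spread evenly
#' over the remaining `n-1`, the joint matrix has `p/n` on the diagonal and
#' `(1-p)/(n(n-1))` off it, and its mutual information reduces to
#' `mi = p*log2(p*n) + (1-p)*log2((1-p)*n/(n-1))` bits.
#'
#' @param p Probability of correct decoding, `1/n <= p <= 1` (vectorised).
#' @param n Number of alternatives.
#' @return Mutual information in bits.
#' @export
mi_from_p <- function(p, n) {
  if (any(p < 1 / n - 1e-12 | p > 1 + 1e-12))
    stop("'p' must lie in [1/n, 1]")
  p <- pmin(pmax(p, 1 / n), 1)
  t1 <- ifelse(p > 0, p * log2(p * n), 0)
  q <- 1 - p
  t2 <- ifelse(q > 0, q * log2(q * n / (n - 1)), 0)
  t1 + t2
}

#' Invert the confusion-matrix information for the decoding probability
#'
#' Solves `mi_from_p(p, n) = mi` for `p` on `[1/n, 1]`, where the map is
#' strictly increasing.  Values of `mi` slightly outside `[0, log2 n]`
#' (Monte Carlo noise) are clipped with a warning.
#'
#' @param mi Mutual information in bits (vectorised).
#' @param n Number of alternatives.
#' @return Correct-decoding probability in `[1/n, 1]`.
#' @export
p_from_mi <- function(mi, n) {
  hi <- log2(n)
  if (any(mi < -1e-9 | mi > hi + 1e-9))
    warning("'mi' outside [0, log2 n]; clipped")
  mi <- pmin(pmax(mi, 0), hi)
  vapply(mi, function(m) {
    if (m <= 0) return(1 / n)
    if (m >= hi) return(1)
    stats::uniroot(function(p) mi_from_p(p, n) - m,
                   interval = c(1 / n, 1), tol = 1e-12)$root
  }, 0)
}

#' Expected categorical information given the stimulus information
#'
#' The categorical information a neuron would attain if its stimulus
#' information were spread equally over all stimuli and the stimulus ordering
#' segregated the categories perfectly.  The stimulus information is first
#' converted to a correct-decoding probability ([p_from_mi()]), the implied
#' symmetric `n x n` joint confusion matrix is built, its rows and columns
#' are summed within categories, and the grouped matrix's mutual information
#' `H_row + H_col - H_tot` is returned.
#'
#' @param mi_stim Stimulus mutual information in bits (vectorised).
#' @param category_sizes Integer vector of stimuli per category
#'   (`sum = n`).
#' @return Expected categorical information in bits.
#' @export
expected_category_info <- function(mi_stim, category_sizes) {
  n <- sum(category_sizes)
  idx <- rep(seq_along(category_sizes), category_sizes)
  vapply(mi_stim, function(mi) {
    if (!is.finite(mi)) return(NA_real_)
    p <- p_from_mi(mi, n)
    q <- (1 - p) / ((n - 1) * n)
    J <- matrix(q, n, n)
    diag(J) <- p / n
    G <- rowsum(t(rowsum(J, idx)), idx)
    .entropy_bits(rowSums(G)) + .entropy_bits(colSums(G)) -
      .entropy_bits(as.numeric(G))
  }, 0)
}

#' Floor reference: categorical information of random categories
#'
#' Averages the cumulative categorical information over `n_perm` random
#' stimulus-to-category assignments that preserve the true category sizes.
#' This is the information a category variable carries when its labels are
#' unrelated to the neural responses beyond what stimulus identity provides.
#'
#' @param rates A `binned_rates` object.
#' @param grouping The true category map (only its label multiset is used).
#' @param mc An [mc_params()] object; permutation `k` uses seed
#'   `mc$seed + 7919 * k`.
#' @param n_perm Number of random assignments (default 10).
#' @param t_max Last bin to compute.
#' @param bias_correct Passed to [cumulative_info()]; off by default — the
#'   floor's uncertainty is dominated by the grouping draw, and skipping the
#'   per-permutation jackknife keeps its cost proportionate.
#' @return Numeric vector: per-bin floor value (bits), with attribute
#'   `per_permutation` (matrix permutations x bins).
#' @export
floor_category_info <- function(rates, grouping, mc = mc_params(),
                                n_perm = 10, t_max = ncol(rates$mu),
                                bias_correct = FALSE) {
  stopifnot(inherits(rates, "binned_rates"), n_perm >= 1)
  grouping <- category_map(grouping)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(mc$seed)
  perms <- lapply(seq_len(n_perm), function(k)
    stats::setNames(sample(unname(grouping)), names(grouping)))
  reps <- do.call(rbind, lapply(seq_len(n_perm), function(k) {
    mck <- mc
    mck$seed <- mc$seed + 7919L * k
    cumulative_info(rates, grouping = perms[[k]], mc = mck,
                    bias_correct = bias_correct, t_max = t_max)$info
  }))
  structure(colMeans(reps), per_permutation = reps)
}

#' Ceiling reference for categorical information
#'
#' The categorical information attainable if all stimulus information served
#' category discrimination: the stimulus cumulative information, capped at
#' `log2(n_c)`.
#'
#' @param ci_stim Stimulus cumulative information per bin (bits), or an
#'   [info_series()].
#' @param n_c Number of categories.
#' @return Per-bin ceiling (bits).
#' @export
ceiling_category_info <- function(ci_stim, n_c) {
  if (inherits(ci_stim, "info_series")) ci_stim <- ci_stim$info
  pmin(ci_stim, log2(n_c))
}

#' Categorical Information Index series
#'
#' Places the actual categorical cumulative information `CCI` between its
#' floor, expected and ceiling references on a 0-2 scale:
#' `CII = (CCI - Floor)/(Exp - Floor)` below the expected value and
#' `CII = 1 + (CCI - Exp)/(Ceil - Exp)` above it.  An index of 0 means the
#' categories look random, 1 means category coding is exactly what shared
#' stimulus information predicts, 2 means responses are invariant within
#' categories.
#'
#' @param cci Actual categorical cumulative information per bin (bits), or an
#'   [info_series()].
#' @param floor,expected,ceiling Reference values per bin (bits).
#' @param time_ms Optional bin end times.
#' @param clip Clip the index into `[0, 2]` (default `TRUE`); the unclipped
#'   value is always kept in column `cii_raw`.
#' @return A data frame of class `cii_series` with columns `time_ms`, `cci`,
#'   `floor`, `expected`, `ceiling`, `cii`, `cii_raw`.  Bins with degenerate
#'   reference spacing (`< 1e-9` bits) or inconsistent references carry `NA`;
#'   attributes `n_clipped` and `n_violated` count the affected bins.
#' @export
cii_series <- function(cci, floor, expected, ceiling,
                       time_ms = seq_along(floor), clip = TRUE) {
  if (inherits(cci, "info_series")) {
    if (missing(time_ms)) time_ms <- cci$time_ms
    cci <- cci$info
  }
  stopifnot(length(floor) == length(cci), length(expected) == length(cci),
            length(ceiling) == length(cci))
  raw <- rep(NA_real_, length(cci))
  violated <- is.finite(floor) & is.finite(expected) & is.finite(ceiling) &
    !(floor <= expected + 1e-9 & expected <= ceiling + 1e-9)
  for (b in seq_along(cci)) {
    if (any(!is.finite(c(cci[b], floor[b], expected[b], ceiling[b]))))
      next
    # a reference inversion (estimation noise) voids only the branch it
    # enters; the other branch's references may still be perfectly ordered
    if (cci[b] < expected[b]) {
      den <- expected[b] - floor[b]
      if (den >= 1e-9) raw[b] <- (cci[b] - floor[b]) / den
    } else {
      den <- ceiling[b] - expected[b]
      if (den >= 1e-9) raw[b] <- 1 + (cci[b] - expected[b]) / den
    }
  }
  cl <- if (clip) pmin(pmax(raw, 0), 2) else raw
  structure(data.frame(time_ms = time_ms, cci = cci, floor = floor,
                       expected = expected, ceiling = ceiling,
                       cii = cl, cii_raw = raw),
            n_clipped = sum(cl != raw, na.rm = TRUE),
            n_violated = sum(violated),
            class = c("cii_series", "data.frame"))
}

#' Time-averaged Categorical Information Index
#'
#' Mean of the defined index values over a time window (default the 50-300 ms
#' span in which categorical invariance peaks).
#'
#' @param series A [cii_series()].
#' @param t_start,t_end Window bounds in ms (bins with
#'   `t_start < time_ms <= t_end` contribute).
#' @param use_raw Average the unclipped index (default `FALSE`).
#' @return Scalar mean index.
#' @export
cii_time_average <- function(series, t_start = 50, t_end = 300,
                             use_raw = FALSE) {
  stopifnot(inherits(series, "cii_series"))
  v <- if (use_raw) series$cii_raw else series$cii
  sel <- series$time_ms > t_start & series$time_ms <= t_end
  v <- v[sel]
  if (!any(is.finite(v)))
    stop("no defined index values in [", t_start, ", ", t_end, "] ms")
  mean(v[is.finite(v)])
}

#' Full Categorical Information Index computation
#'
#' Convenience wrapper: computes the stimulus and categorical cumulative
#' information (same Monte Carlo seeds so shared structure cancels), the
#' floor (random-category), expected ([expected_category_info()]) and ceiling
#' references, and assembles the [cii_series()].
#'
#' @param rates A `binned_rates` object.
#' @param grouping Category map (defaults to the categories stored in
#'   `rates`).
#' @param mc An [mc_params()] object.
#' @param n_perm Random assignments for the floor.
#' @param t_max Last bin to compute.
#' @param bias_correct Passed to [cumulative_info()].
#' @param clip Passed to [cii_series()].
#' @return A `cii_series` with attributes `ci_stim` and `cci` (the two
#'   underlying [info_series()]).
#' @export
categorical_information_index <- function(rates, grouping = rates$categories,
                                          mc = mc_params(), n_perm = 10,
                                          t_max = ncol(rates$mu),
                                          bias_correct = TRUE, clip = TRUE) {
  grouping <- category_map(grouping)
  ci_stim <- cumulative_info(rates, grouping = NULL, mc = mc,
                             bias_correct = bias_correct, t_max = t_max)
  cci <- cumulative_info(rates, grouping = grouping, mc = mc,
                         bias_correct = bias_correct, t_max = t_max)
  flo <- floor_category_info(rates, grouping, mc = mc, n_perm = n_perm,
                             t_max = t_max)
  sizes <- as.integer(table(grouping))
  expd <- expected_category_info(ci_stim$info, sizes)
  ceil <- ceiling_category_info(ci_stim, length(unique(grouping)))
  out <- cii_series(cci, flo, expd, ceil, time_ms = ci_stim$time_ms,
                    clip = clip)
  attr(out, "ci_stim") <- ci_stim
  attr(out, "cci") <- cci
  out
}
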