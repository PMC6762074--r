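#' Monte Carlo importance-sampling parameters
#'
#' Controls the joint-entropy estimator of [mc_joint_entropy()]: samples are
#' drawn in chunks; after each chunk the between-chunk standard error of the
#' entropy is evaluated and sampling stops once it falls below `se_stop` or
#' the sample budget is exhausted.  If the error still exceeds `se_abort` at
#' the budget, the estimate is flagged unreliable and [cumulative_info()]
#' stops computing later bins.
#'
#' @param chunk Samples per chunk (default 100000).
#' @param se_stop Stopping standard error in bits (default 0.2).
#' @param max_samples Maximum total samples (default 5e6).
#' @param se_abort Unreliability threshold in bits (default 0.6).
#' @param seed Integer seed; per-bin estimates use derived seeds
#'   (`seed + bin index`) so successive bins are independent yet reproducible.
#' @param q_mix Fraction of proposal draws taken from the product of per-bin
#'   marginal mixtures; the remainder is drawn from the stimulus-conditional
#'   mixture itself (defensive component that keeps importance weights
#'   bounded when per-stimulus rates are strongly distinct).  `q_mix = 1`
#'   uses the pure product-of-marginals proposal.
#' @return An object of class `mc_params`.
#' @export
mc_params <- function(chunk = 100000, se_stop = 0.2, max_samples = 5e6,
                      se_abort = 0.6, seed = 1, q_mix = 0.5) {
  if (!(se_stop > 0 && se_stop < se_abort))
    stop("require 0 < se_stop < se_abort")
  if (chunk > max_samples) stop("'chunk' must not exceed 'max_samples'")
  if (q_mix < 0 || q_mix > 1) stop("'q_mix' must lie in [0, 1]")
  structure(list(chunk = as.integer(chunk), se_stop = se_stop,
                 max_samples = as.integer(max_samples), se_abort = se_abort,
                 seed = as.integer(seed), q_mix = q_mix),
            class = "mc_params")
}

#' Cumulative conditional response entropy
#'
#' Under the Poisson assumption, spike counts in successive bins are
#' conditionally independent given the stimulus, so the joint conditional
#' entropy is the exact sum of the per-bin conditional entropies from the
#' first bin through `t_bin`.
#'
#' @param rates A `binned_rates` object.
#' @param t_bin Last bin index (1-based).
#' @param grouping Optional category map for categorical information.
#' @param scheme Prior scheme (see [instantaneous_info()]).
#' @return Conditional entropy `H(Y_1..Y_t | S)` in bits.
#' @export
conditional_cum_entropy <- function(rates, t_bin, grouping = NULL,
                                    scheme = if (is.null(grouping))
                                      "equal_stimulus" else "equal_category") {
  stopifnot(inherits(rates, "binned_rates"),
            t_bin >= 1L, t_bin <= ncol(rates$mu))
  ch <- .channel(rates, grouping, scheme)
  sum(.channel_cond_entropy(ch, seq_len(t_bin)))
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Joint response entropy by Monte Carlo importance sampling
#'
#' Estimates `H(Y_1, ..., Y_t)` of the stimulus-mixture response distribution
#' as the importance-weighted average `-(1/N) sum (p/q) log2 p`, with the
#' exact mixture probability `p(y)` evaluated in log space at every sampled
#' count vector.  The proposal is a defensive mixture: with probability
#' `q_mix` a vector is drawn from the product of the per-bin marginal
#' mixtures (truncated at `r_max`), otherwise a stimulus is drawn from its
#' prior and the vector from that stimulus's product distribution.  The
#' second component guarantees that the stimulus-coherent trajectories which
#' dominate the mixture's mass are sampled at prior rate, keeping the
#' importance weights bounded; `q_mix = 1` gives the pure
#' product-of-marginals proposal.  Sampling proceeds in chunks (see
#' [mc_params()]); the standard error is the between-chunk standard error of
#' the chunk means.
#'
#' @inheritParams conditional_cum_entropy
#' @param mc An [mc_params()] object (its `seed` is used directly; see
#'   [cumulative_info()] for the per-bin seed derivation).
#' @return List with `h` (bits), `se` (bits), `n_samples` and `unreliable`.
#' @export
mc_joint_entropy <- function(rates, t_bin, mc = mc_params(), grouping = NULL,
                             scheme = if (is.null(grouping))
                               "equal_stimulus" else "equal_category") {
  stopifnot(inherits(rates, "binned_rates"), inherits(mc, "mc_params"),
            t_bin >= 1L, t_bin <= ncol(rates$mu))
  ch <- .channel(rates, grouping, scheme)
  bins <- seq_len(t_bin)
  nb <- length(bins)
  nu <- length(ch$prior)
  ny <- dim(ch$logp)[1L]
  # per-bin marginal mixture, renormalised over the truncated support
  qs <- lapply(bins, function(b) {
    p <- as.numeric(matrix(exp(ch$logp[, b, ]), ny, nu) %*% ch$prior)
    p / sum(p)
  })
  logq_marg <- lapply(qs, log)
  # per-(unit, bin) truncated pmfs for the defensive component, renormalised
  zlog <- matrix(0, nu, nb)                       # log truncation mass
  for (u in seq_len(nu)) for (b in seq_len(nb))
    zlog[u, b] <- log(sum(exp(ch$logp[, bins[b], u])))
  zsum <- rowSums(zlog)
  logprior <- log(ch$prior)
  tabs <- lapply(seq_len(nu), function(u) matrix(ch$logp[, bins, u], ny, nb))
  alpha <- mc$q_mix
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(mc$seed)
  chunk_means <- numeric(0)
  n_total <- 0L
  repeat {
    n <- min(mc$chunk, mc$max_samples - n_total)
    if (n <= 0L) break
    comp <- sample.int(nu + 1L, n, replace = TRUE,
                       prob = c(alpha, (1 - alpha) * ch$prior))
    Y1 <- matrix(0L, n, nb)
    im <- which(comp == 1L)
    if (length(im))
      Y1[im, ] <- vapply(seq_len(nb), function(b)
        sample.int(ny, length(im), replace = TRUE, prob = qs[[b]]),
        integer(length(im)))
    for (u in seq_len(nu)) {
      iu <- which(comp == u + 1L)
      if (!length(iu)) next
      Y1[iu, ] <- vapply(seq_len(nb), function(b)
        sample.int(ny, length(iu), replace = TRUE,
                   prob = exp(ch$logp[, bins[b], u] - zlog[u, b])),
        integer(length(iu)))
    }
    idx <- as.vector(Y1 + (rep(seq_len(nb), each = n) - 1L) * ny)
    lp_u <- vapply(seq_len(nu), function(u)
      rowSums(matrix(tabs[[u]][idx], n, nb)), numeric(n))
    lp_u <- matrix(lp_u, n, nu)
    lp <- .logsumexp_rows(sweep(lp_u, 2L, logprior, "+"))
    lq_marg <- rowSums(matrix(vapply(seq_len(nb), function(b)
      logq_marg[[b]][Y1[, b]], numeric(n)), n, nb))
    lq_def <- .logsumexp_rows(sweep(lp_u, 2L, logprior - zsum, "+"))
    lq <- if (alpha >= 1) lq_marg
          else if (alpha <= 0) lq_def
          else .logsumexp_rows(cbind(log(alpha) + lq_marg,
                                     log1p(-alpha) + lq_def))
    chunk_means <- c(chunk_means, -mean(exp(lp - lq) * lp / log(2)))
    n_total <- n_total + n
    # a between-chunk SE needs a few chunks to be trustworthy (>= 4)
    if (length(chunk_means) >= 4L) {
      se <- stats::sd(chunk_means) / sqrt(length(chunk_means))
      if (se <= mc$se_stop || n_total >= mc$max_samples) break
    } else if (n_total >= mc$max_samples) break
  }
  se <- if (length(chunk_means) >= 2L)
    stats::sd(chunk_means) / sqrt(length(chunk_means)) else NA_real_
  list(h = mean(chunk_means), se = se, n_samples = n_total,
       unreliable = isTRUE(se > mc$se_abort) || is.na(se))
}

#' Cumulative mutual information over growing bin sequences
#'
#' For every bin `t`, `CI_t = H(Y_1..Y_t) - H(Y_1..Y_t|S)`: the joint response
#' entropy is estimated by Monte Carlo importance sampling
#' ([mc_joint_entropy()], with seed `mc$seed + t` at bin `t`) and the
#' conditional term is exact ([conditional_cum_entropy()]).  With a
#' `grouping`, both terms use the category-averaged conditional
#' distributions, giving the categorical cumulative information.  Once a
#' bin's Monte Carlo error is flagged unreliable, later bins are not computed
#' and `abort_bin` is set on the returned series.
#'
#' When the `binned_rates` carry jackknife replicates and
#' `bias_correct = TRUE`, the Monte Carlo estimation is repeated for every
#' delete-one rate replicate (same derived seed), the per-bin values are
#' jackknife bias-corrected, and the standard error combines the jackknife
#' variance with the Monte Carlo between-chunk variance in quadrature.
#'
#' @inheritParams conditional_cum_entropy
#' @param mc An [mc_params()] object.
#' @param bias_correct Apply jackknife bias correction when replicates are
#'   available (default `TRUE`).
#' @param t_max Last bin to compute (default: all bins).
#' @return An [info_series()], kind `"cumulative_stim"` or
#'   `"cumulative_cat"`.
#' @export
cumulative_info <- function(rates, grouping = NULL, mc = mc_params(),
                            scheme = if (is.null(grouping))
                              "equal_stimulus" else "equal_category",
                            bias_correct = TRUE, t_max = ncol(rates$mu)) {
  stopifnot(inherits(rates, "binned_rates"))
  nb <- as.integer(t_max)
  info <- se <- rep(NA_real_, nb)
  abort <- NA_integer_
  use_jk <- !is.null(rates$jackknife) && bias_correct
  for (t in seq_len(nb)) {
    mct <- mc
    mct$seed <- mc$seed + t
    est <- mc_joint_entropy(rates, t, mct, grouping, scheme)
    if (est$unreliable) { abort <- t; break }
    ci <- est$h - conditional_cum_entropy(rates, t, grouping, scheme)
    if (use_jk) {
      reps <- .jackknife_info(rates, function(r) {
        e <- mc_joint_entropy(r, t, mct, grouping, scheme)
        e$h - conditional_cum_entropy(r, t, grouping, scheme)
      })
      info[t] <- .jk_correct_vec(ci, reps)
      se[t] <- sqrt(.jk_se_vec(reps)^2 + est$se^2)
    } else {
      info[t] <- ci
      se[t] <- est$se
    }
  }
  info_series(time_ms = seq_len(nb) * rates$bin_ms, info = info, se = se,
              kind = if (is.null(grouping)) "cumulative_stim"
                     else "cumulative_cat",
              abort_bin = abort)
}

# exact joint entropy over a set of consecutive bins by full enumeration
.enum_joint_entropy <- function(ch, bins, max_states = 2e6) {
  ny <- dim(ch$logp)[1L]
  if (ny^length(bins) > max_states)
    stop("enumeration over ", ny, "^", length(bins),
         " outcomes exceeds the budget; lower r_max or the number of bins")
  nu <- length(ch$prior)
  L <- matrix(ch$logp[, bins[1L], ], ny, nu)
  for (b in bins[-1L]) {
    S <- nrow(L)
    L <- L[rep(seq_len(S), times = ny), , drop = FALSE] +
      matrix(ch$logp[, b, ], ny, nu)[rep(seq_len(ny), each = S), ,
                                     drop = FALSE]
  }
  lp <- .logsumexp_rows(sweep(L, 2L, log(ch$prior), "+"))
  -sum(exp(lp) * lp) / log(2)
}

#' Joint response entropy under a Markov-chain approximation
#'
#' Approximates `H(Y_1, ..., Y_t)` by the chain decomposition
#' `H(Y_1..Y_m) + sum_{u>m} H(Y_u | Y_{u-1}..Y_{u-m})` with history `m =
#' order`, each term evaluated exactly from the stimulus-mixture joint
#' distributions of `order+1` consecutive bins.  Because conditioning on a
#' truncated history discards longer-range dependencies of the mixture, this
#' approximation overestimates the true joint entropy and hence upper-bounds
#' the cumulative information.
#'
#' @inheritParams conditional_cum_entropy
#' @param order Markov order (1-4 typical); `order >= t_bin` reproduces the
#'   exact entropy.
#' @param max_states Enumeration budget for `(r_max+1)^(order+1)` outcomes.
#' @return Approximate joint entropy in bits.
#' @export
markov_joint_entropy <- function(rates, t_bin, order = 1, grouping = NULL,
                                 scheme = if (is.null(grouping))
                                   "equal_stimulus" else "equal_category",
                                 max_states = 2e6) {
  stopifnot(inherits(rates, "binned_rates"), order >= 1L,
            t_bin >= 1L, t_bin <= ncol(rates$mu))
  order <- min(as.integer(order), t_bin)
  ch <- .channel(rates, grouping, scheme)
  h <- .enum_joint_entropy(ch, seq_len(min(order, t_bin)), max_states)
  if (t_bin > order) {
    for (u in (order + 1L):t_bin) {
      h <- h + .enum_joint_entropy(ch, (u - order):u, max_states) -
        .enum_joint_entropy(ch, (u - order):(u - 1L), max_states)
    }
  }
  h
}

#' Exact running-window information
#'
#' Computes, at every bin `t`, the exact mutual information carried by the
#' joint spike counts of the last `n_bins` bins (full enumeration of all
#' count vectors).  Because information outside the window is discarded, this
#' underestimates the cumulative information and serves as a lower reference
#' bound; with `n_bins = 1` it reduces to the instantaneous information.
#'
#' @inheritParams conditional_cum_entropy
#' @param n_bins Window length in bins (default 4).
#' @param max_states Enumeration budget.
#' @return An [info_series()], kind `"window_stim"` or `"window_cat"`.
#' @export
exact_window_info <- function(rates, n_bins = 4, grouping = NULL,
                              scheme = if (is.null(grouping))
                                "equal_stimulus" else "equal_category",
                              max_states = 2e6) {
  stopifnot(inherits(rates, "binned_rates"), n_bins >= 1L)
  ch <- .channel(rates, grouping, scheme)
  nb <- ncol(rates$mu)
  info <- vapply(seq_len(nb), function(t) {
    w <- max(1L, t - as.integer(n_bins) + 1L):t
    .enum_joint_entropy(ch, w, max_states) -
      sum(.channel_cond_entropy(ch, w))
  }, 0)
  info_series(time_ms = seq_len(nb) * rates$bin_ms, info = info,
              se = rep(0, nb),
              kind = if (is.null(grouping)) "window_stim" else "window_cat")
}
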