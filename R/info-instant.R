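#' Stimulus prior probabilities
#'
#' Two priors are supported: `"equal_stimulus"` gives every stimulus
#' probability `1/n_s`; `"equal_category"` makes every category equally
#' probable and splits its mass uniformly over the `k_i` stimuli it contains,
#' i.e. `p(s_i) = 1/(k_i * n_c)`.
#'
#' @param categories Named character vector mapping stimulus id to category
#'   (see [category_map()]), or a `spike_train_set`.
#' @param scheme `"equal_stimulus"` or `"equal_category"`.
#' @return Named numeric vector of probabilities summing to 1.
#' @export
stimulus_priors <- function(categories,
                            scheme = c("equal_stimulus", "equal_category")) {
  scheme <- match.arg(scheme)
  categories <- category_map(categories)
  n_s <- length(categories)
  if (scheme == "equal_stimulus") {
    p <- rep(1 / n_s, n_s)
  } else {
    k <- table(categories)[categories]            # size of own category
    p <- 1 / (as.numeric(k) * length(unique(categories)))
  }
  stats::setNames(p, names(categories))
}

# -sum p log2 p with the p log p -> 0 limit for vanishing mass
.entropy_bits <- function(p) {
  p <- p[p > 1e-300]
  -sum(p * log2(p))
}

#' Entropy of a truncated Poisson count distribution (closed form)
#'
#' Evaluates, in bits, the closed-form entropy of a Poisson spike count with
#' mean `mu`:
#' `H = mu*(1/ln 2 - log2 mu) + exp(-mu) * sum_{y=0}^{r_max} mu^y log2(y!)/y!`.
#' The factorial series is truncated at `r_max`; the truncation is guarded by
#' requiring the Poisson mass up to `r_max` to be numerically 1.
#'
#' @param mu Expected count(s) per bin (vectorised).
#' @param r_max Truncation count (default 20).
#' @return Entropy in bits (same length as `mu`).
#' @export
poisson_entropy <- function(mu, r_max = 20) {
  if (any(mu <= 0)) stop("'mu' must be positive")
  if (any(1 - stats::ppois(r_max, max(mu)) > 1e-12))
    stop("truncated Poisson mass below 1 - 1e-12; raise r_max above ", r_max)
  y <- 0:r_max
  lf2 <- lfactorial(y) / log(2)                   # log2(y!)
  s <- outer(mu, y, function(m, yy) exp(yy * log(m) - lfactorial(yy))) %*%
    lf2
  as.numeric(mu * (1 / log(2) - log2(mu)) + exp(-mu) * s)
}

#' Entropy of a Poisson mixture at one bin
#'
#' Entropy in bits of `p(y) = sum_i p(s_i) Pois(y; mu_i)`, summed over
#' `y = 0..r_max`.
#'
#' @param mus Per-stimulus expected counts at the bin.
#' @param priors Stimulus probabilities (default uniform).
#' @param r_max Truncation count.
#' @return Scalar entropy in bits.
#' @export
mixture_entropy <- function(mus, priors = rep(1 / length(mus), length(mus)),
                            r_max = 20) {
  if (any(mus <= 0)) stop("'mus' must be positive")
  if (abs(sum(priors) - 1) > 1e-12) stop("priors must sum to 1")
  if (any(1 - stats::ppois(r_max, max(mus)) > 1e-12))
    stop("truncated Poisson mass below 1 - 1e-12; raise r_max above ", r_max)
  y <- 0:r_max
  pmf <- outer(mus, y, function(m, yy) stats::dpois(yy, m))
  .entropy_bits(as.numeric(priors %*% pmf))
}

# Build the conditional-probability "channel" used by all estimators:
# log pmf tables (r_max+1 x bins x units) and unit priors.  Units are
# stimuli (grouping = NULL) or categories (conditional pmfs averaged within
# category with uniform within-category weights).
.channel <- function(rates, grouping = NULL,
                     scheme = if (is.null(grouping)) "equal_stimulus"
                              else "equal_category") {
  stopifnot(inherits(rates, "binned_rates"))
  mu <- rates$mu
  y <- 0:rates$r_max
  if (is.null(grouping)) {
    p_s <- stimulus_priors(rates$categories, scheme)
    logp <- array(NA_real_, c(length(y), ncol(mu), nrow(mu)))
    for (i in seq_len(nrow(mu)))
      logp[, , i] <- outer(y, mu[i, ], function(yy, m)
        stats::dpois(yy, m, log = TRUE))
    list(logp = logp, prior = unname(p_s), labels = rownames(mu))
  } else {
    grouping <- category_map(grouping)
    if (!all(rownames(mu) %in% names(grouping)))
      stop("grouping does not cover all stimuli")
    grouping <- grouping[rownames(mu)]
    cats <- unique(grouping)
    logp <- array(NA_real_, c(length(y), ncol(mu), length(cats)))
    for (k in seq_along(cats)) {
      members <- which(grouping == cats[k])
      pm <- 0
      for (i in members)
        pm <- pm + outer(y, mu[i, ], stats::dpois) / length(members)
      logp[, , k] <- log(pm)
    }
    list(logp = logp, prior = rep(1 / length(cats), length(cats)),
         labels = cats)
  }
}

# per-bin conditional entropy sum_u prior_u H(Y_b | u) from channel tables
.channel_cond_entropy <- function(ch, bins) {
  vapply(bins, function(b) {
    sum(vapply(seq_along(ch$prior), function(u) {
      ch$prior[u] * .entropy_bits(exp(ch$logp[, b, u]))
    }, 0))
  }, 0)
}

# per-bin marginal mixture entropy from channel tables
.channel_marg_entropy <- function(ch, bins) {
  vapply(bins, function(b) {
    p <- as.numeric(exp(ch$logp[, b, , drop = FALSE])[, 1L, ] %*% ch$prior)
    .entropy_bits(p)
  }, 0)
}

#' Instantaneous mutual information per analysis bin
#'
#' Computes `I_t = H(Y_t) - H(Y_t|S)` at every bin from per-bin Poisson means,
#' where `H(Y_t)` is the entropy of the stimulus mixture and `H(Y_t|S)` the
#' prior-weighted conditional entropy.  With a `grouping`, the
#' stimulus-conditional distributions are first averaged within each category
#' (uniform within-category weights) and the information about the category
#' variable is returned, with categories equally probable.
#'
#' When the `binned_rates` carry jackknife replicates, the per-bin values are
#' jackknife bias-corrected and a jackknife standard error is attached.
#'
#' @param rates A `binned_rates` object.
#' @param grouping Optional stimulus-to-category map ([category_map()] or a
#'   named character vector); `NULL` for stimulus information.
#' @param scheme Prior scheme (see [stimulus_priors()]); defaults to
#'   `"equal_stimulus"` for stimulus information and `"equal_category"` for
#'   categorical information.
#' @param bias_correct Apply jackknife bias correction when replicates are
#'   available (default `TRUE`).
#' @return An [info_series()] with one row per bin.
#' @export
instantaneous_info <- function(rates, grouping = NULL,
                               scheme = if (is.null(grouping))
                                 "equal_stimulus" else "equal_category",
                               bias_correct = TRUE) {
  stopifnot(inherits(rates, "binned_rates"))
  point <- .instant_point(rates, grouping, scheme)
  nb <- length(point)
  se <- rep(NA_real_, nb)
  info <- point
  if (!is.null(rates$jackknife) && bias_correct) {
    reps <- .jackknife_info(rates, function(r) .instant_point(r, grouping,
                                                             scheme))
    info <- .jk_correct_vec(point, reps)
    se <- .jk_se_vec(reps)
  }
  info_series(time_ms = seq_len(nb) * rates$bin_ms, info = info, se = se,
              kind = if (is.null(grouping)) "instantaneous_stim"
                     else "instantaneous_cat")
}

# point estimate of I_t per bin (no resampling)
.instant_point <- function(rates, grouping, scheme) {
  ch <- .channel(rates, grouping, scheme)
  bins <- seq_len(ncol(rates$mu))
  .channel_marg_entropy(ch, bins) - .channel_cond_entropy(ch, bins)
}

# rebuild binned_rates from each jackknife replicate and apply `fun`;
# returns a matrix replicates x values
.jackknife_info <- function(rates, fun) {
  jk <- rates$jackknife
  M <- nrow(jk[[1L]])
  do.call(rbind, lapply(seq_len(M), function(j) {
    mu_j <- do.call(rbind, lapply(jk, function(m) m[j, ]))
    rownames(mu_j) <- rownames(rates$mu)
    rj <- .binned_rates(mu_j, rates$bin_ms, rates$r_max, rates$categories,
                        mass_tol = rates$mass_tol %||% 1e-12)
    fun(rj)
  }))
}
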