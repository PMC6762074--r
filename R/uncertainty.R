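#' Jackknife bias correction
#'
#' Standard delete-one jackknife bias-corrected estimate
#' `M * theta_full - (M-1) * mean(theta_deleteone)`, which removes the
#' leading `O(1/M)` bias of plug-in information estimates caused by the
#' limited number of trials.
#'
#' @param full_estimate The estimate computed from all `M` trials (bits).
#' @param delete_one_estimates The `M` delete-one replicate estimates.
#' @return Bias-corrected estimate (bits).
#' @export
jackknife_bias_correct <- function(full_estimate, delete_one_estimates) {
  reps <- delete_one_estimates
  bad <- !is.finite(reps)
  if (any(bad)) {
    warning(sum(bad), " non-finite jackknife replicate(s) excluded")
    reps <- reps[!bad]
  }
  M <- length(reps)
  if (M < 2L) stop("at least 2 finite jackknife replicates are required")
  M * full_estimate - (M - 1) * mean(reps)
}

# vectorised forms for per-bin series: reps is a replicates x bins matrix
.jk_correct_vec <- function(full, reps) {
  M <- nrow(reps)
  M * full - (M - 1) * colMeans(reps)
}
.jk_se_vec <- function(reps) {
  M <- nrow(reps)
  mu <- colMeans(reps)
  sqrt((M - 1) / M * colSums((t(t(reps) - mu))^2))
}

#' Bootstrap standard error of repeated jackknife estimates
#'
#' Given `NB` repetitions of the full bias-corrected estimation pipeline
#' (trials resampled with replacement and, for cumulative values, Monte Carlo
#' samples re-drawn), returns `sqrt(sum(var(I_JN))/NB^2)`, i.e. the sample
#' standard deviation of the repetitions divided by `sqrt(NB)`.
#'
#' @param jackknife_corrected_reps Numeric vector of `NB >= 2` repetition
#'   values (bits).
#' @return Standard error (bits).
#' @export
bootstrap_error <- function(jackknife_corrected_reps) {
  nb <- length(jackknife_corrected_reps)
  if (nb < 2L) stop("at least 2 bootstrap repetitions are required")
  sqrt(stats::var(jackknife_corrected_reps) / nb)
}

#' Significance mask for an information series
#'
#' A bin is significant when its information exceeds `threshold` times its
#' local standard error (default 3).
#'
#' @param series An [info_series()].
#' @param threshold Multiple of the local SE (default 3).
#' @return List with `significant` (logical per bin, `NA` where info or SE is
#'   undefined) and `any_significant`.
#' @export
significance_mask <- function(series, threshold = 3) {
  stopifnot(inherits(series, "info_series"))
  sig <- series$info > threshold * series$se
  list(significant = sig, any_significant = isTRUE(any(sig, na.rm = TRUE)))
}

#' Bootstrap an information pipeline over trials
#'
#' Resamples trials with replacement within each stimulus `nb_boot` times,
#' applies `fun` (which should map a [spike_train_set()] to an
#' [info_series()], typically via rate estimation with jackknife bias
#' correction) to each resample, and combines the repetitions: the estimate
#' is the mean across repetitions and the per-bin standard error follows
#' [bootstrap_error()].
#'
#' @param x A `spike_train_set`.
#' @param fun Function `spike_train_set -> info_series`.
#' @param nb_boot Number of bootstrap repetitions (default 20).
#' @param seed Integer seed for the trial resampling.
#' @return An `info_series` with bootstrap standard errors, plus attribute
#'   `replicates` (repetitions x bins matrix).
#' @export
bootstrap_info_series <- function(x, fun, nb_boot = 20, seed) {
  stopifnot(inherits(x, "spike_train_set"), nb_boot >= 2)
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  reps <- NULL
  template <- NULL
  for (b in seq_len(nb_boot)) {
    xb <- x
    for (id in names(xb$stimuli)) {
      tr <- xb$stimuli[[id]]$trials
      xb$stimuli[[id]]$trials <- tr[sample.int(length(tr), replace = TRUE)]
    }
    sb <- fun(xb)
    if (is.null(reps)) {
      reps <- matrix(NA_real_, nb_boot, nrow(sb))
      template <- sb
    }
    reps[b, ] <- sb$info
  }
  est <- colMeans(reps)
  se <- apply(reps, 2L, function(v) bootstrap_error(v[is.finite(v)]))
  out <- info_series(time_ms = template$time_ms, info = est, se = se,
                     kind = attr(template, "kind"))
  attr(out, "replicates") <- reps
  out
}
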