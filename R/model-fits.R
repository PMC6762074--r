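#' Exponential fit to a cumulative-information curve
#'
#' Fits `CI(t) = k * I_max * (1 - exp(-(t - dt)/tau))` for `t > dt` (0
#' before) by bounded nonlinear least squares, multi-started from a 3x3x3
#' grid of initial values.  `k` is the saturation fraction relative to the
#' maximum achievable information `I_max` (`log2` of the number of stimuli or
#' categories), `tau` the accumulation time constant in ms and `dt` the
#' latency in ms.
#'
#' @param series An [info_series()] (cumulative information); only finite
#'   bins before any abort are used.
#' @param i_max Maximum achievable information in bits.
#' @return An `exp_fit` object: list with `k`, `tau`, `dt`, `i_max`, `mse`
#'   (bits^2), `k300` (model value at 300 ms over `i_max`) and `converged`.
#' @export
fit_exponential <- function(series, i_max) {
  stopifnot(inherits(series, "info_series"), i_max > 0)
  ok <- is.finite(series$info)
  t <- series$time_ms[ok]
  y <- series$info[ok]
  if (length(y) < 5L) stop("at least 5 defined bins are required for the fit")
  window <- max(series$time_ms)
  model <- function(par, tt)
    ifelse(tt > par[3L],
           par[1L] * i_max * (1 - exp(-(tt - par[3L]) / par[2L])), 0)
  obj <- function(par) mean((y - model(par, t))^2)
  lower <- c(0, 1e-3, 0)
  upper <- c(1, 10 * window, window)
  k0 <- min(1, max(y) / i_max)
  starts <- expand.grid(k = pmax(1e-3, k0 * c(0.5, 1, 1.5)),
                        tau = c(0.2, 0.5, 1.5) * window,
                        dt = c(0, 0.1, 0.3) * window)
  best <- NULL
  conv <- FALSE
  for (r in seq_len(nrow(starts))) {
    par0 <- pmin(pmax(as.numeric(starts[r, ]), lower), upper)
    fit <- try(stats::optim(par0, obj, method = "L-BFGS-B",
                            lower = lower, upper = upper), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      conv <- conv || fit$convergence == 0L
    }
  }
  if (is.null(best)) stop("exponential fit failed from every start")
  par <- best$par
  out <- structure(list(k = par[1L], tau = par[2L], dt = par[3L],
                        i_max = i_max, mse = best$value, converged = conv),
                   class = "exp_fit")
  out$k300 <- k_at(out, 300)
  out
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "exp_fit: k = %.3f, tau = %.0f ms, dt = %.0f ms (I_max = %.2f bits)\n",
    x$k, x$tau, x$dt, x$i_max))
  cat(sprintf("  k300 = %.3f, MSE = %.4g bits^2%s\n", x$k300, x$mse,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Relative model information at a fixed time
#'
#' Evaluates the fitted saturation model relative to `I_max`:
#' `k * (1 - exp(-(t - dt)/tau))` for `t > dt`, 0 otherwise.  At the default
#' `t_ms = 300` this is the fraction of the maximum achievable information
#' accumulated by 300 ms, a behaviorally relevant point for call durations.
#'
#' @param fit An `exp_fit` from [fit_exponential()].
#' @param t_ms Evaluation time in ms (default 300).
#' @return Fraction in `[0, 1]`.
#' @export
k_at <- function(fit, t_ms = 300) {
  stopifnot(inherits(fit, "exp_fit"))
  if (t_ms <= fit$dt) return(0)
  fit$k * (1 - exp(-(t_ms - fit$dt) / fit$tau))
}
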