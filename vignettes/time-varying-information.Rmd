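---
title: "Time-varying information for spike trains: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying information for spike trains: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvinfo)
```

## The problem

A neuron listening to a set of discrete stimuli — here, communication calls
drawn from a vocal repertoire, each labelled with a behavioural category such
as its call-type — emits spike trains that unfold over a few hundred
milliseconds. Two questions drive this package:

1. How much information about *which stimulus* (or which *category*) was
   presented is available in the response up to time $t$, and how does that
   information accumulate?
2. How much of the stimulus information is *category-invariant*, i.e.
   reflects the category rather than the particular stimulus?

Direct (histogram-based) information estimates over joint spike-count
vectors are hopeless at the trial counts of a typical experiment (about ten
presentations per stimulus), so the package takes a parametric route: the
response is modelled as an inhomogeneous Poisson process, fully described by
a per-stimulus time-varying rate.

## Model and estimators

Spike counts $y_t$ are taken in consecutive 10 ms analysis bins (60 bins in
the default 600 ms window; 10 ms corresponds to a 50 Hz Nyquist limit, and
the diagnostics below check that almost none of the response dynamics lives
above that). Given stimulus $s_i$, the count in bin $t$ is Poisson with mean
$\mu_{s_i}(t)$, and counts in different bins are conditionally independent.

**Instantaneous information.** $I_t = H(Y_t) - H(Y_t\mid S)$, with the
conditional entropy evaluated by a closed form for the entropy of a Poisson
variable (factorial series truncated at $R_{max} = 20$ counts; the truncated
mass must be 1 to within $10^{-12}$ or the computation refuses to proceed)
and the response entropy evaluated from the Poisson-mixture distribution
$p(y_t) = \sum_i p(s_i)\,p(y_t\mid s_i)$.

**Cumulative information.** $CI_t = H(Y_t,\dots,Y_0) -
H(Y_t,\dots,Y_0\mid S)$. The conditional term is an exact sum of per-bin
entropies (conditional independence). The joint response entropy has no
closed form because bins are *unconditionally* dependent — the rates of
different stimuli are correlated in time — and its outcome space grows as
$(R_{max}+1)^{t}$. Three estimators are provided:

* `mc_joint_entropy()` — Monte Carlo importance sampling (the reference
  estimator). See the numerical notes below for the proposal distribution.
* `markov_joint_entropy()` — a chain-rule decomposition conditioning on a
  bounded history (orders 1–4). Truncating the history discards long-range
  dependencies of the mixture and therefore *overestimates* the joint
  entropy, giving an upper bound on the cumulative information.
* `exact_window_info()` — full enumeration over a short running window
  (default 4 bins). Information outside the window is discarded, giving a
  lower reference bound.

The test suite asserts the resulting ordering (window $\le$ MC $\le$ Markov
at matched times, within Monte Carlo error) on a temporally correlated
synthetic neuron, and checks the Monte Carlo estimator against exhaustive
enumeration on small cases.

**Categorical information.** For category labels, the stimulus-conditional
distributions are first averaged within each category (uniform weights
within a category) and the same machinery runs on the category-conditional
distributions, with categories equally probable. Two stimulus priors are
available: `equal_stimulus` ($1/n_s$) and `equal_category`
($1/(k_i n_c)$ for a stimulus in a category of size $k_i$). The package
defaults to `equal_stimulus` for stimulus information and `equal_category`
for categorical information, matching the treatment of category
probabilities as $1/n_c$.

## Rate estimation

`estimate_rate()` pools the spike times of all trials of a stimulus and
smooths them with Gaussian kernels. The bandwidth is chosen by minimising an
unbiased estimate of the mean integrated squared error for a Poisson point
process,
$C(w) = \sum_{i,j}\phi_{\sqrt2 w}(t_i-t_j) - 2\sum_{i\ne j}\phi_w(t_i-t_j)$,
over a 40-point log-spaced grid, then adapted locally: the optimisation is
repeated in overlapping windows of five global bandwidths (50% overlap) and
the per-sample bandwidth is linearly interpolated. Kernels are renormalised
over the response window, so no rate mass is lost at the onset — errors
there would feed straight into the information at early bins. Pairwise sums
are evaluated on 1 ms binned counts via an FFT autocorrelation, so the cost
is independent of spike count.

Degenerate inputs follow fixed fallback rules: with zero spikes across all
$M$ trials the rate is the constant $1/(2 M N)$ per sample ($N$ = number of
rate samples), with exactly one spike $1/(M N)$; the estimated rate is also
floored at the zero-spike constant everywhere so Poisson likelihoods stay
finite.

`integrate_to_bins()` converts rates into per-bin expected counts and
enforces a lower bound of $1/20$ expected counts per 10 ms bin — the
mirror image of the $R_{max}=20$ per-bin truncation at the other end of the
count range. The floor is exposed as `mu_floor` for users who prefer a
per-sample convention.

Recovery quality is measured, not assumed: on the three model-neuron
archetypes (constant-rate coding, onset-latency coding, temporal coding;
amplitudes up to 0.1 spikes/ms, 10 trials), the mean absolute rate error of
the estimator is below 0.02 spikes/ms (`kde_validation_error()`; asserted in
the tests).

## Uncertainty

Plug-in information estimates from $\sim$10 trials are positively biased:
sampling noise makes estimated rates differ across stimuli even when the
true rates are identical. Three tools address this:

* **Jackknife bias correction** (`jackknife_bias_correct()`):
  $M\hat\theta - (M-1)\overline{\hat\theta_{(j)}}$ over delete-one rate
  estimates, removing the leading $1/M$ bias. Delete-one replicates reuse
  the full-sample bandwidth profile by default: re-optimising the bandwidth
  per replicate makes the replicate a non-smooth functional of the data and
  empirically leaves about half of the null bias in place, while the fixed
  profile removes most of it (and is considerably faster). The literal
  re-optimisation is available via
  `jackknife_rates(reuse_bandwidth = FALSE)`.
* **Standard errors**: instantaneous series carry the jackknife standard
  error; cumulative series combine the jackknife variance with the Monte
  Carlo between-chunk variance in quadrature. The full trial-bootstrap
  recipe (`bootstrap_error()`, `bootstrap_info_series()`, default
  `nb_boot = 20`) wraps any pipeline and reports
  $\sqrt{\mathrm{var}(\hat\theta_b)/N_B}$; because it multiplies the whole
  pipeline cost by $N_B$, it is an explicit user choice rather than the
  default error path.
* **Significance**: a bin is significant when its information exceeds three
  local standard errors (`significance_mask()`); exponential fits are only
  attempted when some bin of the stimulus cumulative information is
  significant.

Even after correction a small positive residual remains on null data
(about 0.002 bits at $M = 10$ in our simulations — second-order bias the
delete-one jackknife cannot reach), which is why "centered at zero" is
asserted at the 0.005-bit level in the tests rather than against a
vanishing standard error.

## Numerical choices

* **Monte Carlo proposal.** The entropy is an expectation under the
  stimulus-mixture distribution $p$. A product of per-bin marginal mixtures
  is a natural proposal, but when per-stimulus rates are strongly distinct
  it fails catastrophically at longer integration times: the
  stimulus-coherent count trajectories that carry most of $p$'s mass have
  probability $\sim(1/n_s)^{B}$ under the independent proposal over $B$
  bins, so importance weights explode and the standard error never falls.
  The package therefore uses a defensive mixture: with probability `q_mix`
  (default 0.5) a vector is drawn from the product of marginals, otherwise
  a stimulus is drawn from its prior and the vector from that stimulus's
  own product distribution. The weights are then bounded, the estimator
  remains unbiased, and `q_mix = 1` recovers the pure product-of-marginals
  proposal for comparison.
* **Chunked stopping.** Samples arrive in chunks of 100 000; the standard
  error is the between-chunk standard error of the chunk means (at least
  two chunks are always drawn). Sampling stops at 0.2 bits, caps at
  5 000 000 samples, and an error above 0.6 bits at the cap flags the bin
  unreliable — later bins of that series are not computed and the series
  records `abort_bin`.
* **Seeds.** Every stochastic operation takes an explicit integer seed and
  restores the global RNG state. Cumulative series derive the seed for bin
  $t$ as `seed + t`, so bins are independent yet the whole series is
  reproducible bit for bit.
* **Log-space.** All pmf products and mixture sums use log probabilities
  with log-sum-exp; $p\log p$ terms below $10^{-300}$ contribute zero.
* **Inversion.** `p_from_mi()` inverts the confusion-matrix information
  with `stats::uniroot` on $[1/n, 1]$ (the map is strictly increasing) at
  tolerance $10^{-12}$, rather than a hand-rolled bisection.
* **Exponential fits.** `fit_exponential()` minimises the mean squared
  error of $k I_{max}(1 - e^{-(t-dt)/\tau})$ with `optim(L-BFGS-B)` from a
  $3\times3\times3$ grid of starts, bounds $k\in[0,1]$,
  $\tau\in(0, 10\,T]$, $dt\in[0, T]$.

## The categorical information index

`categorical_information_index()` places the categorical cumulative
information between three references: a **floor** (mean categorical
information over random stimulus-to-category assignments preserving the
category sizes; default 10 assignments — there is no canonical count, so it
is configurable), an **expected** value (the categorical
information implied by the stimulus information if it were spread evenly
over stimuli and the response ordering segregated categories perfectly;
computed by inverting the symmetric confusion-matrix information and
grouping the implied joint matrix), and a **ceiling** (the stimulus
information capped at $\log_2 n_c$). The index is 0 at the floor, 1 at the
expected value, 2 at the ceiling; values outside $[0,2]$ from estimation
noise are clipped, with the raw value kept alongside. The references are
computed from the bias-corrected stimulus series when jackknife replicates
are available.

A caution for very small designs: with four stimuli in two categories of
two there are only three distinct groupings, so the random-assignment floor
receives a $1/3$ contribution from the rank-sorted grouping and can land
close to the expected reference. When the floor-to-expected spacing is
comparable to the estimation error the lower branch of the index is
ill-conditioned; `cii_series()` marks bins with spacing below $10^{-9}$
bits undefined, and the per-bin `cii_raw` column lets users judge
stability. At realistic scale (many stimuli per category) the spacing is
wide and the index is stable.

## The simulator and what passing tests show

`model_neuron()` builds the archetypes used throughout: `rate` (four
constant rates, default 0.01–0.09 spikes/ms), `onset` (equal bursts of 0.2
spikes/ms for 200 ms at latencies 0/100/200/300 ms over a 0.005 spikes/ms
baseline), `temporal` (equal bursts at disjoint times), `invariant`
(within-category identical rates, 0.01 vs 0.2 spikes/ms across categories)
and `interleaved` (constant rates 0.01/0.04/0.08/0.12 spikes/ms with
rank-interleaved labels). Published figures show these regimes only
graphically; the defaults are documented choices that reproduce the
qualitative regimes, not pixel measurements. `sample_spikes()` draws
per-millisecond Poisson counts with uniform jitter — exact for
piecewise-constant rates.

Simulated data are conditionally independent Poisson by construction. They
share none of the awkward features of real recordings: no refractoriness,
no trial-to-trial gain drift (non-zero noise correlations), no deviation
from Poisson count statistics, and no unequal trial counts unless
requested. Passing the end-to-end tests therefore certifies the estimation
machinery *given the model*, and the `diagnostics` module exists precisely
to check the model against data: a bootstrap goodness-of-fit test of the
per-bin Poisson distribution (delete-one means, Benjamini–Hochberg control
across bins), time-resolved Fano factors, noise and stimulus correlations
between successive bins, and two spectral checks (split-half coherence
information below 50 Hz, cumulative rate power below 50 Hz) that justify
the 10 ms resolution. For the split-half coherence correction we use the
derivation relating the coherence of two $M/2$-trial averages to the
single-trial/mean coherence,
$\gamma^2_{AR} = [1 + \tfrac{M}{2}(\sqrt{1/\gamma^2_{12}} - 1)]^{-1}$,
with Welch estimation (200 ms Hann windows, 50% overlap). Three numerical
safeguards matter here: the raw segment-averaged coherence is debiased by
its $1/K$ independence floor ($K$ = averaged segments); the coherence is
averaged over the random halvings *before* the strongly nonlinear
trial-count correction; and frequencies whose coherence cannot be
distinguished from zero at the 5% level of the null distribution
$P(\hat\gamma^2 > x) \approx (1-x)^{K-1}$ are set to zero — otherwise
rectified estimation noise integrates into a spurious broadband
information rate that can dominate weak signals. The Fano factor uses the
$n-1$ sample variance (a population toggle is provided).

Problem sizes in the shipped tests are deliberately desk-scale — e.g. 8–20
simulation seeds per null check, 200-sample bootstrap nulls, enumeration
oracles at $R_{max}\le 7$ over 2–3 bins — chosen so the whole suite
exercises every estimator end to end in minutes on one core.

## Known limitations

* The Poisson assumption is a modelling floor: for data with informative
  noise correlations the estimates are lower bounds on the true
  information.
* The adaptive bandwidth optimiser is this package's own implementation of
  MISE-optimal Gaussian smoothing with local adaptation; it is validated
  by rate-recovery bounds, not by bit-exact agreement with any particular
  published implementation.
* Renewal-process generalisations (gamma, inverse-Gaussian interval
  statistics) and multi-neuron joint information are out of scope.
* The exact-window and Markov estimators are exponential in window/order
  and guarded by an explicit state budget (`max_states`).

## A worked example

```{r example, eval = FALSE}
spec <- model_neuron("invariant", amplitudes = c(0.02, 0.18))
spk  <- sample_spikes(spec, n_trials = 10, seed = 1)
br   <- integrate_to_bins(rate_ensemble(spk), bin_ms = 10, r_max = 25)

inst <- instantaneous_info(br)                       # bias-corrected I_t
ci   <- cumulative_info(br, mc = mc_params(seed = 1))
cii  <- categorical_information_index(br, mc = mc_params(seed = 1))
fit  <- fit_exponential(ci, i_max = log2(4))

significance_mask(ci)$any_significant
cii_time_average(cii, 50, 300)
fit$k300
```
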