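# tvinfo

Time-varying mutual information for neural spike trains under
inhomogeneous Poisson models.

## What this is for

Neurons that encode discrete sensory objects — say, communication calls
drawn from a species' vocal repertoire, each belonging to a behavioural
category (its call-type) — accumulate evidence about stimulus identity over
hundreds of milliseconds. `tvinfo` estimates, from trial-structured spike
times, how that evidence grows: the **instantaneous** mutual information
between stimulus (or category) and the spike count of each 10 ms bin, and
the **cumulative** information carried by the joint counts from stimulus
onset through each bin. It is aimed at systems neuroscientists who have a
modest number of trials (~10 per stimulus) over a large stimulus set, where
direct histogram estimators are hopeless but a rate-parametric model is
defensible — and it ships the diagnostics to check that defence.

## The model and the estimators

Spike counts in 10 ms bins are modelled as conditionally independent
Poisson variables with per-stimulus time-varying means μ<sub>s</sub>(t),
estimated by a locally adaptive Gaussian kernel density estimator from the
pooled trials. Then

- I<sub>t</sub> = H(Y<sub>t</sub>) − H(Y<sub>t</sub>|S), with closed-form
  Poisson entropies (counts truncated at R<sub>max</sub> = 20);
- CI<sub>t</sub> = H(Y<sub>t</sub>,…,Y<sub>0</sub>) −
  H(Y<sub>t</sub>,…,Y<sub>0</sub>|S), where the conditional term is an
  exact sum and the joint response entropy is estimated by Monte Carlo
  importance sampling with a defensive mixture proposal, chunked sampling
  and explicit reliability flags. A Markov-chain estimator (upper bound)
  and an exact running-window estimator (lower bound) bracket it.

Jackknife resampling of the rate estimates removes the leading 1/M
information bias; trial bootstrap gives standard errors; a bin is
"significant" above three local standard errors.

For category coding, the **Categorical Information Index (CII)** locates
the categorical cumulative information between a random-grouping floor (0),
the value expected from the stimulus information alone (1), and the
invariance ceiling (2): CII ≈ 2 means stimuli within a category evoke
interchangeable responses. Exponential fits CI(t) ≈
k·I<sub>max</sub>(1−e<sup>−(t−dt)/τ</sup>) summarise accumulation speed (τ,
in ms) and saturation (k, k<sub>300</sub>).

A simulator (`model_neuron()`, `sample_spikes()`) generates the rate-,
onset- and temporal-coding archetypes plus category-invariant and
rank-interleaved neurons used to validate every estimator end to end.

## A worked example

```r
library(tvinfo)

spec <- model_neuron("invariant", amplitudes = c(0.01, 0.2))  # 2 categories x 2 stimuli
spk  <- sample_spikes(spec, n_trials = 10, seed = 1)
# r_max comfortably above the largest expected count per 10 ms bin (~2)
br   <- integrate_to_bins(rate_ensemble(spk), bin_ms = 10, r_max = 25)

ci  <- cumulative_info(br, mc = mc_params(chunk = 20000, seed = 1), t_max = 10)
cii <- categorical_information_index(br, mc = mc_params(chunk = 20000, seed = 1),
                                     n_perm = 3, t_max = 10)
round(ci$info[10], 2);  round(cii$cii[10], 2)
```

```
[1] 1.01
[1] 2
```

By 100 ms this neuron has extracted the full bit that separates its
two response classes (the two categories; stimuli within a category are
identical by construction), and the index sits at its ceiling of 2: all of
the stimulus information is category information, the signature of an
invariant categorical response. For the same rates with labels assigned at
random, the categorical information falls to the floor reference and the
index collapses.

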