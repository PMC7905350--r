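---
title: "Two-level sparse RBF networks for EEG fatigue detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level sparse RBF networks for EEG fatigue detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegfatigue)
```

This vignette is the package's own account of its science: the model and its
assumptions, the parameters that matter, what the synthetic generator
emulates (and deliberately does not), and the numerical choices made where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The classification problem

The package targets two-state brain-state discrimination from multichannel
EEG: 32 channels sampled at 500 Hz, recorded in two labeled sessions per
subject (alert vs. fatigue, 20 minutes each). The classification unit is a
10-second epoch — a 32 x 2,000 matrix after downsampling to 200 Hz. The
physiological signal of interest is the posterior alpha rhythm (8-13 Hz),
whose power rises with drowsiness; everything in the pipeline is built
around making that power contrast accessible to a kernel classifier.

## 2. Preprocessing

1. **Resampling 500 to 200 Hz.** The factor is rational but not integer
   (2/5), so resampling is polyphase: zero-stuff by p = 2, apply a
   Kaiser-windowed (beta = 5) sinc low-pass with cutoff at the tighter
   Nyquist limit and half-length `10 * max(p, q)` taps, compensate the
   linear-phase delay, keep every q = 5th sample. Duration is preserved to
   within one output sample, in-band sinusoid amplitude to well under 1%
   (tested by least-squares sinusoid fits).
2. **Band-pass 1-45 Hz, 4th-order Butterworth.** Designed by bilinear
   transform of the analog prototype with frequency pre-warping (the
   coefficients were cross-checked against an independent reference
   implementation during development; the tests freeze analytic magnitude
   bounds instead). The filter runs zero-phase (forward-backward) by
   default, doubling the effective roll-off — an offline pipeline has no
   causality constraint. A single causal pass is available
   (`zero_phase = FALSE`). The protocol order is downsample-then-filter;
   `filter_first = TRUE` gives the numerically safer reverse order.
3. **Epoching.** Half-open windows `[kW, (k+1)W)`, trailing remainder
   discarded, every epoch inheriting the recording label.

## 3. Per-epoch PCA features

Each epoch is reduced *by its own* PCA with channels as observations and
time points as variables: the epoch is column-mean-centered (equivalent to
a common-average reference at each time point) and projected onto its top
`r = 10` principal directions; the 32 x 10 score matrix is flattened
channel-major into a 320-vector. Ten components keep well over 80% of
per-epoch variance on the synthetic world (the suite asserts > 0.80).

Two design points deserve emphasis:

* **Sign convention.** PCA components are sign-ambiguous. Fixing signs on
  the time-domain directions would anchor them to an epoch-specific noise
  realization, leaving every epoch's feature signs effectively random and
  destroying comparability across epochs. Signs are therefore fixed on the
  *score columns* — across-channel spatial patterns, which are stable from
  epoch to epoch: the largest-magnitude entry of each score column is made
  positive.
* **Centering interacts with topography.** Because centering removes the
  cross-channel mean at every time point, a spatially near-uniform rhythm is
  almost invisible to these features; only the spatially *structured* part
  of a pattern survives. This drove the synthetic generator's focal alpha
  profile (section 6).

Features are min-max normalized to [-1, 1] per feature, fitted on training
rows only and frozen into the model (`norm_stats`); z-scoring is available.
Normalization prevents the downstream network weights from being dominated
by scale, at the cost of re-amplifying low-variance score columns — a real
effect users should know about when interpreting kernel distances.

## 4. The lower-level learner

With every training input a candidate center, the network is linear in the
parameters: `y = Phi theta + e`, `Phi[k, i] = exp(-||x(k) - x(i)||^2 /
rho)`. Orthogonal decomposition `Phi = W A` (W orthogonal columns, A unit
upper triangular, `g = A theta`) turns subset selection into a sequence of
independent one-dimensional problems. The selection cost is

`J = e'e + lambda g'g + beta * sum_i (-log w_i'w_i)`

— a ridge penalty on the orthogonal weights plus a D-optimality term that
favors well-conditioned (high-information) regressor subsets. Admitting
candidate `i` lowers `J` by `(w_i'w_i + lambda) g_i^2 + beta log(w_i'w_i)`
with `g_i = w_i'y / (w_i'w_i + lambda)`; normalizing by `y'y` gives the
combined error reduction ratio used for greedy selection. Selection stops
when no remaining candidate has a positive ratio — the D-optimality term is
what makes automatic termination work at `lambda = 0`.

Numerical choices:

* Modified Gram-Schmidt with an **unconditional re-orthogonalization pass**
  on each winning column; orthogonality of `W` is asserted below 1e-8 on
  every trace.
* Candidates whose orthogonalized squared norm falls below
  `1e-12 * trace(Phi'Phi) / N` sit out a step (the log term diverges there);
  if none remain usable, selection stops.
* Ties in the selection ratio break toward the lowest candidate index, so
  selection order is deterministic.
* `max_terms` defaults to N but exists as a guard: with
  `lambda = beta = 0` the stopping rule may never trigger before
  interpolation.
* Targets are coded 0/1 exactly as the labels (fatigue = 1), matching the
  strict `> 0.5` decision rule; the boundary value maps to alert.
* Weights solve `A theta = g` by back-substitution. Note that `theta`
  minimizes `||y - Phi_s theta||^2 + lambda ||A theta||^2` — the ridge acts
  on the *orthogonal* weights `g`, not on `theta` itself, so the plain ridge
  normal equations reproduce it only at `lambda = 0`. The tests verify the
  g-penalized form against an independent augmented-QR oracle.
* One consequence of Gaussian candidates worth recording: `Phi` has unit
  diagonal, so every candidate column norm is at least 1 and
  `log(w'w) >= 0` at step one. A large `beta` therefore *rewards* early
  selection rather than suppressing it; an empty selection can only arise
  from degenerate targets or non-Gaussian regression matrices.

## 5. The upper level

Only `K = [lambda, rho, beta]` remains to tune. A global-best particle
swarm (size 15, 30 iterations by default) minimizes validation MSE of the
continuous outputs, `f(K) = (1/n_c) sum (y - yhat)^2`. Defaults follow the
classic inertia-weight formulation: inertia linearly decreasing 0.9 to 0.4,
`c1 = c2 = 2`, velocities clamped to 20% of each range, positions clamped
to bounds with the velocity zeroed on the clamped dimension. `lambda` and
`beta` span seven orders of magnitude and are searched on a log10 scale;
`rho` is linear. One explicitly seeded RNG stream is consumed in fixed
particle order, so runs are bit-reproducible; evaluation counts are exactly
`p` (initialization) plus `p * T`. A particle whose network cannot be
trained is penalized with `+Inf` rather than aborting the search. The final
model is refit on the training set at the best `K` (identical to the best
particle's network by determinism of the lower level).

The search bounds (`lambda, beta` in [1e-7, 1], `rho` in [1, 220]) are part
of the published protocol and assume min-max-normalized features; `rho` is
a squared-distance scale, so if features are not normalized to [-1, 1] the
upper bound must be rescaled.

## 6. The synthetic world

The study's recordings are not deposited, so the package carries a
generator that emulates the *statistical structure the classifier relies
on*, with every parameter explicit:

* **Background**: 8 latent 1/f^2.5 sources mixed through smooth
  Gaussian-bump spatial patterns (volume conduction proxy) with decaying
  strengths (0.75^j), normalized to per-channel RMS 14. The steep exponent
  concentrates background power below the alpha band — large total power,
  little inside 8-13 Hz — which is what reconciles a realistic power budget
  with the alpha-power contrast law below. The decaying strengths give the
  background a stable eigenstructure, so per-epoch PCA orders its
  components consistently.
* **Alpha rhythm**: 8-13 Hz filtered noise, 70% of its variance shared
  across channels, modulated by a spindle-scale log-normal envelope
  (`exp(0.25 z)`, `z` band-limited to 0.1-1 Hz) and shaped by a focal
  posterior profile `0.15 + 0.85 exp(-(pos-1)^2 / (2 * 0.15^2))`, peak RMS
  11 (baseline). The envelope timescale matters twice: seconds-scale
  waxing/waning mimics alpha spindles, and it converges within an epoch and
  within a session, so a session carries no idiosyncratic power fingerprint
  (with one recording per state, a slow envelope would let a classifier
  identify the *recording* rather than the state — at `effect_size = 0`
  this inflated accuracy far above chance until the envelope was moved to
  the spindle scale).
* **State effect**: the fatigue state multiplies the alpha amplitude by
  `1 + effect_size` (default 0.5) — nothing else differs between states, so
  the alpha band-power ratio converges to `(1 + effect_size)^2` and
  `effect_size = 0` is an exact negative control.
* **Subjects**: per-subject log-normal base amplitude (sdlog 0.2), shared
  between a subject's two states.
* **Sensor noise**: white, SD 1.5.

What the generator does *not* emulate: electrode geometry (channel
"position" is an index), artifacts (blinks, EMG, line noise),
non-stationarity across a session, theta/beta band changes with fatigue,
and any nonlinear dynamics. A green end-to-end test therefore establishes
that the pipeline recovers a posterior alpha-power contrast of the stated
effect size from spatially correlated noise — not that it would reach the
same accuracy on clinical recordings.

The focal alpha profile and the correlated background are not cosmetic:
per-epoch PCA column-centering cancels spatially uniform patterns, and
independent-channel background noise would spread variance over all 31
principal components, violating the > 0.80 kept-variance property that the
feature design assumes. Both choices match the phenomenology they stand in
for (occipital alpha focus; volume-conducted background).

## 7. Evaluation protocol

Confusion counts use positive class = fatigue; sensitivity TP/(TP+FN),
specificity TN/(TN+FP), accuracy (TP+TN)/total, reported as percentages
(displays round to 2 decimals; JSON keeps full precision). ROC sweeps
thresholds over the unique scores; AUC is trapezoidal and equals the
Mann-Whitney pair statistic with ties counted one half (property-tested).
Cross-validation is stratified 6-fold; fold SD uses the sample (n-1)
convention. Per-fold vectors are exposed so users can run any significance
test externally.

Two protocol variants exist for the swarm's fitness set inside
cross-validation:

* **Default (study protocol)**: the held-out fold doubles as the swarm's
  validation set. This reproduces the published procedure but carries a
  selection bias — 450 swarm evaluations pick hyperparameters partly for
  that fold, which measurably inflates accuracy on small folds (~60% at
  zero effect on the scaled synthetic study).
* **Three-way split** (`tune_fraction` in `make_tllh_trainer()`): a
  stratified tuning split is carved out of the training rows, the reported
  fold never touches the search, and the final network is refit on all
  training rows at the selected hyperparameters. The acceptance suite uses
  this variant for both effect arms; at zero effect it returns chance.

Whether the published 6-fold protocol re-ran the swarm per fold is not
stated; this package re-runs it per fold with fold-derived seeds.

## 8. Scaling of the shipped checks

The full stated world (6 subjects x 2 x 20 min at 500 Hz) is the package
default but needs gigabytes of signal; the acceptance checks run a scaled
study — 2 subjects x 600 s per state (60 epochs per state per subject) —
while keeping the published learner settings (swarm 15, 30 iterations, 6
folds, 5/6-1/6 split proportions). Counting invariants are checked at the
full duration with 2 channels (epoch counts do not depend on channel
count). The end-to-end checks complete in a few minutes on one CPU.

## 9. Known limitations

* EDF input is not implemented (no reader available in the supported
  dependency set); recordings travel as delimited matrices with a JSON
  sidecar.
* The learner is single-output with Gaussian bases only; scores are not
  calibrated probabilities.
* `lambda` for the fixed-hyperparameter baseline must be user-supplied (the
  published baseline estimated it by a Bayesian evidence procedure that is
  out of scope here).
* Selection cost is O(N^3) in the training-set size; practical up to a few
  hundred epochs per fit, which covers the intended protocol.
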