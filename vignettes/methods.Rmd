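---
title: "Methods: transparent landing-pattern recognition and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transparent landing-pattern recognition and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`landlrp` is a pipeline for asking *where* in a set of lower-limb waveforms
the signal that separates two movement conditions lives. This vignette
documents the models and procedures behind each stage, the tunable
parameters, the numerical conventions, and what the synthetic benchmark
does and does not establish.

## 1. The data model

A trial is a point on an 18-channel × 101-node grid: 3 joints × 3
anatomical planes × {angle, moment}, each channel time-normalised to
nodes 0..100 representing 0–100 % of the landing phase. Channel order is
fixed package-wide (joint-major: ankle, knee, hip; then plane: sagittal,
frontal, transversal; then angle before moment) and all flattened feature
matrices are channel-major with node varying fastest; `channel_table()`
is the single source of truth and the relevance module inverts the map
exactly.

Because the motivating study's motion-capture data are not deposited, the
package carries a first-class generator instead. Trial `t` of subject `s`
in class `c` on channel `k` is

```
x_{t,s,c,k}(·) = b_k(·) + u_{s,k}(·) + e_{t,k}(·) + 1[c = after] · δ_k(·)
```

* `b_k`: a fixed smooth base curve per channel (sum of `basis_order = 3`
  sinusoidal harmonics with coefficients drawn once from a constant seed,
  so the "anatomy" is the same in every dataset). Amplitudes are of order
  one throughout the phase axis — deliberately, so that no phase region is
  systematically favoured by input magnitude when relevance is computed on
  null data.
* `u_{s,k}`: a smooth per-subject offset field with pointwise SD
  `subject_sd`, *shared between the subject's two classes*. This emulates
  stable individual movement signatures and makes the design genuinely
  paired.
* `e_{t,k}`: smooth per-trial noise with pointwise SD `trial_sd`.
* `δ_k`: the summed class-difference templates (`effect_template`),
  boxcar or raised-cosine bumps over half-open phase windows
  `[start, end)`; node `i` is phase `i` %.

Noise fields are white noise convolved with a Gaussian kernel
(`noise_fwhm = 10` nodes) and normalised to unit pointwise variance, not
i.i.d. node noise: random-field-theory thresholds assume differentiable
residual fields, and the variance decomposition
(between-subject ≈ `subject_sd²`, within-subject ≈ `trial_sd²`) stays
exact because the normalisation is pointwise.

**Stated world.** Defaults are 56 subjects × 5 trials per class (280 + 280
trials) matching the motivating design. The scaled-down benchmark used in
the acceptance checks is 16 subjects × 3 trials with one boxcar effect on
the knee sagittal angle over phases [15, 25), amplitude 2.0 against
`subject_sd = 0.3`, `trial_sd = 0.25`. At that operating point the
single-statistic discriminant "mean over the effect window" already has
error ≈ Φ(−a/(2σ)) with σ = √(0.3² + 0.25²) ≈ 0.39, i.e. ≈ 0.5 %, so the
Bayes error of the full problem is below 1 %. These values were fixed
before the acceptance measurements and are not tuned.

**Not emulated:** joint-specific magnitudes and units, angle–moment
coupling, inter-channel correlation beyond the shared subject offset,
heteroscedastic phases (e.g. impact transients), and any interpolation
artefacts of time normalisation. A green benchmark therefore establishes
that the pipeline recovers phase-localised, channel-localised mean
differences under smooth correlated noise — not that it handles real
motion-capture idiosyncrasies.

## 2. Tasks, cross-validation, baseline

The nine tasks select channel subsets: all 18; the 9 angle (kinematics) or
9 moment (kinetics) channels; one joint × 3 planes × 2 quantities (6); one
plane × 3 joints × 2 quantities (6). Fold assignment is by subject:
subjects are shuffled under a seed and dealt round-robin into k = 8 folds,
so fold sizes differ by at most one subject and no subject's trials ever
straddle folds. Rotation r tests on fold r, early-stops on fold
(r+1) mod k, and trains on the remaining six; over the k rotations every
subject is tested exactly once. The Zero-R baseline predicts the training
majority class, ties resolving to the documented class order
(`before_fatigue` first); on the generator's balanced designs it sits at
50 %.

Per-feature z-scoring is available (`mlp_control(standardize = TRUE)`) and
is fit on training folds only; the default is off so relevance lives on
the original signal scale.

## 3. The classifier

One hidden layer of width `min(64, n_features)` with tanh activation and a
linear 2-unit output (argmax decision) is the smallest architecture that
satisfies the transparency requirements while classifying all nine tasks;
depth, width and activation are configurable. Training is full-batch
gradient descent on softmax cross-entropy with a fixed learning rate
(default 0.05 — 0.2 oscillates on the 1818-feature task), ridge penalty
10⁻⁴ for conditioning, at most 500 epochs, and early stopping when the
validation cross-entropy has not improved for 50 epochs (the best-so-far
weights are kept). Everything is deterministic given the seed: weights are
initialised uniformly in ±1/√fan-in from a seeded stream and there is no
minibatch shuffling. Divergence (non-finite scores) aborts with the epoch
in the message rather than returning garbage.

## 4. Relevance propagation

The z-rule redistributes the decomposed class score backward
proportionally to pre-activation contributions. Conventions:

* **Which score:** the *predicted* class's raw (pre-softmax) output score,
  configurable to a fixed class. Explaining the model's own decision is
  the default because that is the question the clinic asks.
* **Stabiliser:** denominators become `z* + ε·sign(z*)` with ε = 10⁻⁹.
  With ε = 0 a vanishing denominator is an error naming layer and neuron.
  The conservation defect this introduces is bounded by ε per unit of
  relevance and is covered by the reported leakage.
* **Biases:** contribute to the denominator but receive no outgoing
  relevance; the absorbed amount is accumulated and reported as `leakage`,
  so `sum(relevance) + leakage = f(x)` holds to floating-point accuracy.
  Assigning bias relevance to inputs instead would manufacture relevance
  at features that played no role.
* **Sign:** kept through propagation. Rectification (clipping negatives to
  zero) happens at averaging time, because the downstream statistics
  (shares of a total, [0, 1] scaling, an RS > 0.7 rule) are only coherent
  for nonnegative contributions. A signed average is available
  (`rectify = FALSE`).

Each held-out trial is explained under the model of the rotation that held
it out, so no trial is ever explained by a network that trained on it.

## 5. Post-processing order and conventions

The pipeline orders the operations **average → smooth → scale**: averaging
first (over correctly classified test trials of both classes, by default)
suppresses per-trial propagation noise before the shape-preserving steps;
scaling last guarantees the final map actually attains 0 and 1. The order
is exposed in the API rather than hard-coded into one function, and the
state flag on `relevance_map` makes misordering an error rather than a
silent bug (smoothing refuses scaled maps, aggregation refuses unscaled
ones).

Smoothing is the explicit 25/50/25 kernel, three passes — the binomial
approximation of a Gaussian filter; the explicit kernel is treated as
authoritative. At the series ends the truncated kernel is renormalised to
sum to one, avoiding endpoint attenuation; a reflecting boundary is
available. Scaling is global min–max over the grid so cross-channel shares
remain comparable; per-channel scaling is available behind a flag for
per-joint visualisation. A constant map scales to all zeros with a warning
(the "lowest relevance everywhere" reading) rather than erroring.

Contribution shares divide by the grid total, so channels, joints, planes
and 1 %-phase bins each partition 100 %. The early-phase window defaults
to phases 1–22 % inclusive (22 of 101 bins; a uniform map gives 21.78 %).
High-relevance extraction uses strict `RS > threshold` (default 0.7) and
reports maximal per-channel runs as inclusive phase intervals.

## 6. Statistical evaluation

Pairing is at subject level: each subject's trials are averaged per class
and the per-node paired t statistic uses the n subject differences
(df = n − 1). Zero-variance nodes yield flagged infinite t and are
excluded from smoothness estimation and cluster bookkeeping.

The family-wise threshold is the standard 1-D random-field construction:
residual smoothness (FWHM) is estimated from the variance of node-wise
normalised residual gradients (per-gap FWHM combined reciprocally, since
resels add; capped at 100 × n_nodes for constant fields), and the critical
value solves `2 (P(T > u) + resels · ρ₁(u)) = α` with
`ρ₁(u) = √(4 ln 2)/(2π) (1 + u²/df)^{−(df−1)/2}` and
`resels = (n_nodes − 1)/FWHM`. Two numerical guards apply: the result is
floored at the pointwise two-tailed quantile (the infinitely-smooth limit)
and capped at the **Bonferroni threshold over the n_nodes lattice points**.
The cap deserves a note: a resel-count Bonferroni bound does *not* dominate
the Euler-characteristic solution (the EC tail density decays more slowly
than any fixed multiple of the t tail), so the cap is taken over lattice
points, which is a genuinely valid family-wise bound for the sampled field
and only engages when the estimated FWHM approaches the node spacing —
exactly the regime where the continuum approximation is invalid. Null
calibration on 2 000 simulated smooth fields (10 pairs, 101 nodes,
FWHM 12) gives a family-wise error within the 0.05 ± 3 binomial-SD band
(measured 0.046–0.052 across seeds; recomputed by the acceptance script).

A sign-flip permutation threshold — the (1 − α) quantile of the max-|t|
distribution under random subject sign flips — is provided as a
distribution-free cross-check and agrees with the RFT value within 10 %
relative on smooth null fields. With fewer than log₂(1/α) subjects it
warns that the permutation resolution is coarse.

Effect sizes use Rosenthal's `r = √(t²/(t²+df))`, banded at 0.5/0.8 into
small/medium/large; the cutoffs are configurable since only "three
regions" is canonical.

The concordance report quantifies, per channel, the Jaccard index and
mutual coverages of {nodes with RS > threshold} versus {supra-threshold
SPM nodes} — turning "the high-RS area coincides with the statistical
result" into a number.

## 7. Effect-window recovery metric

The benchmark's recovery criterion takes, *on the injected channel*, the
nodes whose RS exceeds that channel's 90th percentile (≈ 10 of 101 nodes,
matching the 10-node injected window) and computes Jaccard overlap with
the injected window. A grid-wide top-decile set would be dominated by the
uninjected 17 channels and could not reach the 0.5 criterion even for a
perfect explanation, so the per-channel reading is the meaningful one. The
passing rule (accuracy ≥ 0.95, knee the largest joint share, Jaccard
≥ 0.5) must hold in a majority of 5 fixed seeds.

## 8. Known limitations

* The classifier is intentionally small; no architecture search is
  performed, and SVM/CNN comparators are out of scope (only an adapter
  point exists: anything exposing `forward`-compatible dense layers can be
  explained).
* LRP variants (αβ-rule, flat, deep-Taylor) and convolutional propagation
  are not implemented; the z-rule with ε-stabilisation is the single
  supported rule.
* Real-data headline numbers (task accuracies, joint/plane shares, counts
  of RS > 0.7 variables) are not reproducible without the original
  motion-capture data; the synthetic benchmark checks structure and
  recovery properties, not those values.
* Relevance on standardized inputs (when `standardize = TRUE`) lives on
  the z-scored scale; maps are comparable within a model but not across
  differently-standardized models.
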