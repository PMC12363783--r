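---
title: "Methods: informational connectivity and learning-rate analysis with icnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: informational connectivity and learning-rate analysis with icnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icnet)
```

## The analysis problem

Cognitive-training studies with a pre/post scan ask whether training one
skill (say, a verbal mnemonic or spatial navigation) reorganizes how brain
regions *share information* during a memory task. Classical functional
connectivity correlates region-averaged BOLD time courses; it is blind to
the fine-grained multivoxel patterns that carry stimulus-specific
information. Informational connectivity instead asks: when region A
represents two trials as similar, does region B too? Concretely, each ROI
gets a representational similarity matrix (RSM) of trial-pair pattern
correlations; an edge between two ROIs is the correlation between their
RSM vectors. Collected over all ROI pairs this yields an informational
connectivity matrix (ICM) per participant, session, and context type, and
training effects become group-by-session contrasts on ICM edges.

icnet implements this chain end to end -- single-trial estimation, RSMs,
ICMs, edgewise permutation inference with FDR, connectivity-profile
distances, and the behavioral learning-rate metrics of such studies --
together with a synthetic-data generator whose ground truth exercises
every stage.

## Pipeline stages and their assumptions

### Single-trial estimation (least-squares-separate)

Each trial's response map comes from its own GLM in which the trial of
interest is one regressor and all other trials are pooled into a second
(LS-S), alongside the task's structural regressors (rating periods and
their remainders, ITI or item-recognition periods, instructions), six
motion parameters, one spike regressor per motion-flagged frame, an
intercept, and discrete-cosine drift terms. Task regressors are convolved
with the canonical double-gamma HRF (gamma shapes 6 and 16, scale 1,
undershoot ratio 1/6 -- so the kernel peaks near 5 s). The trial-of-interest
t-value (beta / SE) is the recommended pattern input: it downweights noisy
voxels.

Two numerical points deserve emphasis:

* *The pooled other-trials column is an approximation.* It captures the
  other trials' contribution exactly only when they share one response
  map. The synthetic BOLD generator therefore defaults to a shared per-run
  template (`template_mode = "shared"`), the regime in which noiseless
  planted betas are recovered to machine precision; with `"per_trial"`
  templates the residual trial overlap contaminates estimates slightly,
  which is precisely the trade-off LS-S accepts on real data.
* *Drift handling.* The reference preprocessing applies a nonlinear 100 s
  high-pass before the GLM; icnet instead includes discrete-cosine drift
  regressors with a 100 s cutoff inside each GLM. This is an approximation
  with the same effective passband.

### Motion censoring

Framewise displacement is Power's sum of absolute parameter differences,
rotations converted on a 50 mm sphere; FD of the first frame is defined as
0. Frames with FD > 0.9 mm are censored; a trial is excluded when any
censored frame falls inside its modeled window (the HRF tail is not
included, matching the "duration of the modeled response" convention); a
run is excluded when more than 20% of its volumes are censored or absolute
displacement exceeds half a voxel (1.25 mm at 2.5 mm voxels).

### RSMs and ICMs

RSM entries are Fisher-z-transformed Pearson correlations between trial
patterns, valid only for trial pairs from *different runs* (same-run pairs
are masked to avoid temporal autocorrelation leaking into similarity) and,
at retrieval, only between correctly retrieved trials. Encoding RSMs use
all included trials by default (a `correct_only` flag exists). Three RSM
context types give three ICM types: spatial-only, temporal-only, and
combined ("all trials", still cross-run only). Correlations are clipped at
|r| = 1 - 1e-7 before atanh so duplicate patterns produce a large finite
value with a warning rather than infinity.

Vectorization uses a deterministic row-major upper-triangle order over the
common valid mask, so two ROIs' vectors align entry for entry; ICM edges
are Fisher-z correlations over those aligned vectors. All ROIs of one
participant-session share the trial selection, so a single common mask
serves the whole stack.

### Edgewise inference

The contrast is the Welch two-sample t of per-participant pre-to-post edge
changes (Fisher-z scale): target group versus the two remaining groups
pooled. Welch is used because the pooled group is twice the size of the
target. The null is built by permuting participant group labels -- the
exchangeable unit under the between-group null -- preserving group sizes,
with the add-one estimator p = (1 + #{|t*| >= |t|}) / (1 + n_perm). Both
directions are tested two-sided, with the direction reported from the sign
of t. Benjamini-Hochberg FDR is applied across all edges of one
contrast-by-context family.

A permutation-arithmetic constraint matters when sizing studies: with
n_perm permutations the smallest attainable p is 1 / (n_perm + 1), while
BH at rank k among m edges requires p <= k q / m. With 1,000 permutations
and q = 0.05 a single true edge can therefore only survive when
m <= 50; three jointly significant edges require m <= 150. The power
study in the acceptance suite uses a 12-ROI atlas (66 edges) so that two
or three planted edges at the p floor clear their BH thresholds; the
full-scale analysis with 242 ROIs is exactly why the reference analysis
uses 10,000 permutations.

### Connectivity-profile distance

Per ROI, the spatial and temporal ICM rows (self-edge excluded, masked
entries dropped pairwise) are compared by distance = 1 - r, with both
Pearson and Spearman variants always available since converging results
across both strengthen the claim. Profiles are taken on the Fisher-z scale
for consistency with upstream (a raw-r option exists upstream of the call
by supplying tanh-transformed matrices). Pre/post change is a paired t per
ROI with BH FDR across ROIs. icnet's sign convention is post minus pre
(positive = profiles further apart after training); analyses that order
the pair pre minus post print the same effect with the opposite sign.

### Behavioral metrics

* Training navigation error: 100 x (traveled - shortest) /
  (1.2 x shortest), with the criterion flag at the 120% threshold; the
  numerator choice (traveled - shortest) is consistent with the transfer
  definition, and the threshold factor is exposed as a parameter.
* Transfer navigation error: (traveled - optimal) / optimal.
* Navigation learning rate: -(mean first half - mean last half) /
  (mean first half + mean last half) over an ordered 20-trial session
  (half size 10, parameterized for shorter synthetic runs). It lies in
  [-1, 1] when both half-means are positive and is antisymmetric under
  swapping halves.
* Verbal learning rate: (last trial correct - first trial correct) /
  number of trials; when recall reaches the full list before the 5-trial
  maximum, the denominator is the number of trials *attempted* (the
  natural reading; the alternative -- always 5 -- only shrinks magnitudes).
* Training slope: OLS of daily maximum recalled words on day index,
  fitted separately per window (first five / last five days).
* Correlations: Shapiro-Wilk at alpha 0.05 on both variables selects
  Pearson versus Spearman under `method = "auto"`; covariates are handled
  by residualizing both variables (ranks, for Spearman) with df reduced
  accordingly. Correlation comparisons use the independent-samples Fisher
  z-test, Z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3)); whether a
  dependent-sample variant or covariate-adjusted inputs should enter is a
  judgment the caller makes by choosing the inputs.

## The synthetic world

### Generative model for patterns

Each ROI holds one unit-norm voxel template per context. On trial t the
ROI's pattern is

    gain[t] * rho * sqrt(n_vox) * template + noise,   gain[t] = 1 + gain_sd * f[t]

where across ROIs f[t] ~ N(0, C) for a symmetric unit-diagonal coupling
matrix C. The multiplicative gain model is chosen deliberately: a trial
with a high gain yields a cleaner pattern, hence higher similarity to
other trials, so ROIs with correlated gains have correlated RSM vectors --
informational connectivity detects exactly shared trial-to-trial
representational fidelity. A planted effect on edge (i, j) mixes a shared
standard-normal factor into both ROIs' f with weight a, a^2 =
delta / (1 - delta), moving the pair's gain correlation from c to
c (1 - delta) + delta while preserving unit variance; effects can be
restricted to one context, session, and group. Observed edge z grows
monotonically with delta (property-tested).

Defaults: rho = 0.7, gain_sd = 0.5, noise_sd = 1, retrieval accuracy
p_correct = 0.85, voxel counts uniform on [30, 120]. These were fixed once
to give realistic per-trial pattern correlations (roughly 0.2-0.5 within
context) and per-participant edge-z noise near 0.06-0.09, and are not
revisited per analysis. The design defaults are the full study structure:
3 groups x 24 participants x 2 sessions, 4 encoding runs x 20 trials
(context-pure runs, alternating) and 4 retrieval runs x 25 trials (mixed,
balanced), TR 1.56 s, 6 s trials -- hence 80 encoding and 100 retrieval
trial estimates per participant-session.

What the generator does *not* model: spatial voxel correlations or
smoothness (pattern analyses are voxel-order invariant), physiological or
vascular noise structure, hemodynamic variability across regions,
distortion, or any parameter fitted to real data. A green simulation
therefore establishes the *statistical machinery* -- calibration, power,
monotonicity -- not fidelity to empirical fMRI noise.

### Planting a context-separation effect

For the distance analysis the interesting ground truth is an ROI whose
spatial and temporal connectivity profiles *diverge* after training. The
construction used in the acceptance suite: at pre, the ROI shares planted
coupling with twelve partners in both contexts (correlated profiles, small
distance); at post, the coupling splits -- six partners in the spatial
context only, six different partners in the temporal context only -- so
the two profiles decorrelate and the 1 - r distance rises specifically for
that ROI.

### Behavioral curves

Navigation transfer sessions follow plateau + amplitude x exp(-rate x
trial) error curves with trial noise; training benefit is a reduction of
the early-trial amplitude (faster initial acquisition), which raises the
learning rate toward zero as intended. Verbal transfer recall starts near
the typical memory span (5 words of a 12-word list) and gains about one
word per trial, stopping early on perfect recall; verbal training raises
the per-trial gain at post. The verbal *training* schedule grows the list
by one word on success and shrinks it after two consecutive failures --
the real adaptive schedule follows an unspecified power-law rule, so the
increments are plain parameters rather than a guess at that rule. Planted
improvements are sized so that at the design's n = 24/group the group x
session interaction is recovered essentially always; at 8/group power
drops toward 80%.

## Numerical and design choices, collected

* Fisher-z clip at |r| = 1 - 1e-7 (prevents infinities from duplicates).
* FD of frame 1 is 0; rotation radius 50 mm.
* Add-one permutation p; identity relabellings drawn by chance count
  toward the numerator (conservative, keeps p > 0).
* Degenerate contrasts (zero pooled variance) return t = 0 with a warning
  rather than NaN.
* BH q-values are the monotone-adjusted p-values; rejection uses the
  step-up rule, matching `p.adjust(..., "BH")` to 1e-12 (property-tested).
* All randomness flows from one root seed through named substreams
  (`seed_stream`), so changing, say, the permutation count never changes
  the generated data; identical seeds give byte-identical outputs.
* Runtime containers are plain text (TSV pattern tables, CSV tables, JSON
  config/manifest); no binary formats are required anywhere.

## Known limitations

* `compute_icm` uses the common valid mask across all ROIs of a stack; it
  assumes (and the generator guarantees) one shared trial selection per
  participant-session. Heterogeneous per-ROI masks would need pairwise
  masking.
* The BOLD simulator is single-run and block-regular (fixed ITI and RT
  layouts); it exists to validate the estimator, not to emulate jittered
  acquisitions.
* Mixed-design ANOVAs and Bayes factors are intentionally not
  re-implemented; the pipeline emits tidy tables for external statistical
  software.
* The permutation engine materializes an n_perm x n indicator matrix;
  at 10,000 permutations and a few hundred participants this is still
  only a few MB, but very large designs would want a blocked variant.
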