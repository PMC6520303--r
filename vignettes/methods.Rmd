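---
title: "Methods: test-retest reliability of EEG functional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: test-retest reliability of EEG functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sensor-space EEG functional networks — connectivity matrices built from
phase relations between electrode signals — are candidate biomarkers for
early neurodevelopmental assessment. A biomarker is only useful if it is
stable in the absence of true change: measured twice a week apart on the
same infant, a network characteristic should come back close to its first
value. `eegnetrel` implements the full three-level reliability analysis
of such networks (matrix level, connectivity-measure level, graph level)
together with a synthetic two-session cohort generator, so every stage of
the pipeline can be validated with known ground truth.

## Connectivity model

Signals are decomposed into six bands (delta 0.5–3, theta 3–6, alpha1
6–9, alpha2 9–12, beta 12–25, gamma 25–45 Hz), cut into 5-s epochs
(N = 5 x 512 = 2,560 samples), and 20 epochs are selected at random per
subject and session. Two phase-based estimators are computed per
electrode pair from the Hilbert analytic signal:

* **PLI** = |⟨sign sin Δφ(t)⟩|, the consistency of one channel leading or
  lagging the other. Exactly 0 for zero-lag (volume-conducted) coupling,
  1 for a constant nonzero lag; positively biased in finite samples
  (the bias falls roughly as the square root of the effective sample
  count — visible in the tests at N = 160/640/2,560).
* **dwPLI**, the debiased weighted variant: with per-sample imaginary
  cross-spectral terms `I_k = Im(a_k conj(b_k))` pooled over all epochs,
  `dwPLI = ((ΣI)² − ΣI²) / ((Σ|I|)² − ΣI²)`. The |I| weighting
  suppresses near-zero-lag noise contributions, and the subtraction of
  ΣI² removes the finite-sample bias, so the estimator is centred at 0
  for uncoupled signals (the tests verify |mean| < 0.02 over 500 null
  pairs) and may legitimately go negative. When every `I_k` is zero —
  exactly zero-lag signals, the case both indices are designed to null —
  the denominator vanishes and the value is defined as 0 with a warning.

The per-epoch PLI is averaged across epochs; the dwPLI ratio is formed
once from all pooled samples, which is where its debiasing with respect
to the number of epochs acts.

## Graph metrics

From each full, unthresholded PLI matrix (dwPLI matrices are excluded:
negative weights have no path-length interpretation) we compute

* **Cw**: Onnela-style weighted clustering, weights scaled by the network
  maximum, `t_i = ½ Σ (w_ij w_ih w_jh)^{1/3}`, `Cw = mean 2 t_i /(k_i(k_i−1))`;
* **Lw**: characteristic path length over shortest paths with edge length
  `1/w` (the brain-connectivity-toolbox convention; the length map is a
  design choice, stated here because weighted path length is undefined
  without one);
* normalized forms `Cw/C_rand`, `Lw/L_rand`, where the null model
  shuffles the upper-triangle weights uniformly (preserving the weight
  distribution and global connectivity, destroying topology; 100
  surrogates by default, one shared seeded ensemble per matrix for both
  metrics and the SWI);
* **SWI** = (Cw/C_rand)/(Lw/L_rand).

A uniform complete graph is invariant under weight permutation, so its
normalized metrics are exactly 1 — a useful exactness check. Both raw
metrics match brute-force oracles (triple enumeration; Floyd–Warshall)
to 1e-9 in the tests.

## Reliability statistics

Three levels, for a cohort measured in two sessions:

1. **Matrix level**: Pearson correlation of the vectorized upper
   triangles of a subject's session-1 and session-2 matrices.
2. **Connectivity level**: global connectivity (upper-triangle mean) per
   subject-session feeds a subjects x 2 table; reliability is the
   intraclass correlation `ICC = (MSr − MSe)/(MSr + (k−1) MSe)` in its
   two-way mixed, consistency, single-measure form (ICC(3,1)): MSe is
   the residual after removing subject *and* session effects, so a
   uniform session shift does not count against reliability. The
   literal one-way variant (ICC(1,1)) is available by the `model`
   argument. Unit-wise reliability computes one ICC per edge across
   subjects and summarizes by the median, since per-edge ICC
   distributions are skewed. The top-quartile variant restricts the
   median to the 25% strongest edges of the grand-average network
   (ties at the cutoff are all kept, with a warning).
3. **Graph level**: ICC of Cw, Lw, their normalized forms, and SWI.

ICC values are never clamped — negative estimates are informative.
Interpretation bins follow the test-retest convention: < 0.4 low,
0.4–0.6 mediocre, 0.6–0.75 good, > 0.75 excellent.

Inter-subject variability is the coefficient of variation sd/mean,
computed on session-1 values by default (the session analysed further
downstream); confidence intervals for both ICC and COV come from a
percentile bootstrap that resamples *subjects* with replacement, keeping
each subject's session pair intact (10,000 resamples by default; the
percentile interval was chosen over BCa as the simplest defensible
default and is what the CI machinery's coverage test exercises).

## The synthetic cohort generator

The generator emulates a two-session infant study: 60 subjects, 32
channels, 512 Hz, 150 s per session by default (enough for 30 candidate
epochs), six bands. Its statistical structure:

* Per band, a population-mean coupling matrix; the default places
  channels on a ring with exponentially decaying coupling — a crude but
  serviceable stand-in for distance-dependent sensor coupling.
* Per subject, edge couplings `g = clip(base + subject_sd · Z, 0, 1)`.
  The deviation `Z` mixes a subject-level fingerprint common to all
  edges with edge-specific noise (`fingerprint_share`, default 0.5).
  The shared component is essential: purely independent per-edge
  deviations cancel as 1/sqrt(n_edges) in global connectivity, so a
  cohort would have almost no between-subject variance at the global
  level and global ICC would be near zero *by construction* regardless
  of stability. With the default 0.15 edge-level SD, the inter-subject
  COV of global alpha PLI is about 0.08, in the range reported for
  infant sensor-space cohorts.
* Session 2 deviations are `ρ Z₁ + sqrt(1−ρ²) Z₂'`, so coupling
  deviations correlate `ρ = session_stability` across sessions —
  exactly in expectation, verified on the ground-truth couplings in the
  tests. `session_stability` may also be a per-edge matrix, which is
  how the "stronger edges are more stable" scenario behind the
  top-quartile analysis is constructed.
* Signals: per band, each channel owns a latent narrowband oscillator
  (band-passed white noise, unit SD — *not* a pure sinusoid, whose
  Hilbert phase would be trivially linear and saturate the PLI). Along
  each coupled edge the higher-index channel receives the lower-index
  channel's source shifted by `phase_lag` (default π/2) with weight
  equal to the coupling. The lag must be directed: if both ends
  received each other's lagged source symmetrically, the expected
  imaginary cross-spectrum would be proportional to cos(lag) and vanish
  at π/2, nulling the PLI for every coupled pair. The receiving
  channel's own-source weight is `1 − max(received couplings)`: a
  sum-based reduction collapses to zero once a channel receives many
  moderate edges, which empirically *inverts* the coupling-to-PLI
  relation across subjects; the max rule keeps PLI monotone in every
  coupling while letting a single strong edge dominate (coupling 0.9
  yields PLI ≈ 0.99).
* Bands are summed and white sensor noise added. One global seed expands
  into per-subject substreams (a fixed integer hash), so subject k's
  data are bit-identical whether the cohort has 2 or 60 subjects.

What the generator does **not** emulate: volume conduction and a
realistic forward model (couplings act directly on sensors), nonstationary
band power (the stimuli of a real session modulate power over time; the
generator is stationary), heavy-tailed artifact regimes (only the
explicit `inject_artifacts` jumps and noisy segments), and realistic
electrode geometry. Passing parameter-recovery tests therefore shows the
*estimators and statistics* behave correctly under a controlled truth —
not that real infant EEG meets the model's assumptions.

## Preprocessing choices

* Downsampling (2048 → 512 Hz): zero-phase Butterworth anti-alias
  low-pass at 80% of the target Nyquist, then exact decimation (integer
  ratios) or cubic-spline interpolation. This preserves passband
  amplitude within 1%.
* Broadband filter 0.1–70 Hz, zero-phase forward–backward Butterworth,
  implemented as a high-pass/low-pass cascade: a single band-pass
  section with edges three decades apart places poles too close to the
  unit circle. The high-pass keeps order 3 per pass (order 6 is
  numerically unstable at 0.1 Hz normalized to 512 Hz), the low-pass
  uses order 6 so tones near the upper passband (50 Hz) are preserved
  within ~1% while one octave above (100+ Hz) is attenuated by > 99%.
  Narrow analysis bands use order 3 on both edges.
* Artifact rules are deliberately shallow, mirroring a
  "not deep cleaned" policy: robust-z thresholds on |first difference|
  (jumps, default 8) and on the log of 5-s window variance (default 4,
  per channel; log because window variances are right-skewed, per
  channel because channels legitimately differ in scale). The jump
  scale is estimated per channel from the *lower quartile* of |first
  difference|: the lower quartile reflects the clean portion of a
  channel even when more than half of it is artifactual, so a
  mostly-bad channel cannot mask its own discontinuities — exactly the
  case the bad-channel rule (strictly > 50% flagged) must detect — and
  clean data are essentially never flagged (a median/MAD reference
  trips on tail samples, and one flagged sample voids a whole epoch). Bad channels are removed from
  *both* sessions of a subject, so the retained edge set is identical
  across sessions (and may differ between subjects; edge-level
  statistics use the cross-subject intersection and log the count).
* Epochs are contiguous, non-overlapping, cut from sample 1 after
  band filtering (filtering the continuous record keeps filter
  transients away from epoch edges); artifact-contaminated epochs leave
  the candidate pool *before* the seeded random selection.

## Numerical and degenerate-case policy

* ICC of a table where every subject repeats its value exactly
  (MSe = 0, MSr > 0) is 1, with a warning; a fully constant table has no
  variance to ratio and errors.
* COV with zero mean errors; bootstrap statistics failing on more than
  half the resamples error; a bootstrap CI of a constant statistic
  degenerates to a point interval.
* Disconnected graphs (possible only with exact zero weights) error in
  `characteristic_path_length` rather than returning Inf.
* All stochastic steps (cohort generation, epoch selection, surrogate
  ensembles, bootstrap) take explicit seeds; the pipeline derives
  per-stage substreams from one global seed and reruns bit-identically.

## Problem sizes used in the validation suite

The test suite exercises the pipeline at desk scale, chosen so the
statistical properties are identifiable while the suite stays fast:
parameter-recovery cohorts use 30 subjects x 16 channels x 100 s at
512 Hz with a single alpha band (8–12 Hz) and sensor noise SD 0.2
(the "low noise" regime); the stability grid {0, 0.3, 0.6, 0.9, 1}
shares one seed across cohorts, so the five estimates ride on common
random numbers and the monotonicity check is not confounded by
independent sampling noise. Bootstrap coverage is assessed at the
measurement-table level (200 bivariate-normal cohorts with population
ICC 0.75, n = 60 subjects, 1,000 resamples): coverage is a property of
the CI machinery given exchangeable subject pairs, and table-level
cohorts make 200 replicates tractable. The dwPLI null uses the full
study epoch geometry (20 epochs x 2,560 samples, 500 pairs).

## Known limitations

* No EDF/BDF reader: recordings enter either from the generator or from
  the package's plain-text matrix + JSON sidecar format.
* The generator's coupling-to-PLI map is monotone but nonlinear
  (clipping at [0, 1], phase-mixture saturation), so `session_stability`
  is recovered *ordinally*, not as the literal ICC value at intermediate
  stabilities.
* Graph metrics assume nonnegative weights; dwPLI networks are reported
  at the connectivity level only.
* The pipeline treats sessions as exchangeable beyond a possible
  additive shift (the consistency ICC); systematic session-2 rescaling
  would require an absolute-agreement ICC, which is out of scope.
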