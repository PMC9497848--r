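---
title: "Measuring interpersonal movement synchrony: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring interpersonal movement synchrony: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When two people interact, their body movements coordinate in time. A common
way to quantify this is to film both interactants, convert each person's
visible movement into a motion-energy time series (percentage of a
region-of-interest whose pixels change between frames, at 25 frames per
second), and then compute a synchrony statistic on the bivariate series.
Many such statistics exist, and they do not measure the same thing: some
capture in-phase versus anti-phase coupling, some remove within-person
autocorrelation, some are global and some detect episodic "synchronization
intervals". **movesync** implements a battery of 21 measures spanning these
families, a synthetic-data generator with ground-truth coupling, and the
convergent/predictive validity statistics used to compare measures across a
cohort of dyads.

## Motion-energy extraction

`compute_motion_energy()` counts, for each pair of subsequent frames, the
ROI pixels whose gray value changes by at least 12 of 256 levels. The
comparison is inclusive (`|change| >= 12`); the cut-off is conventionally
stated without strictness, so the boundary case is exposed via the
`inclusive` flag. Counts are standardized by ROI size to a 0--100 scale
(`standardize_series()`) and smoothed with a 5-frame centered moving median
(`smooth_series()`). At the ends of the series the median window shrinks
symmetrically (bandwidth 1 at the first and last frame, 3 at the second,
...), which preserves the series length without inventing data; R's
`runmed()` end rules implement Tukey's end-point rule instead, so the ends
are computed explicitly. ROIs are supplied as mask files rather than drawn
interactively, because interactive ROI drawing is not reproducible in
scripted analyses; a single mask per person is assumed (sub-ROIs can be
summed into one mask beforehand).

## The measure battery

All windowed methods share two numerical conventions: Pearson correlations
are computed by running sums on globally centered series (mathematically
identical, numerically stable), and Fisher's Z uses `atanh` after capping
`|r|` at `1 - 1e-7`, so the perfect correlations that arise in noiseless
fixtures stay finite (the cap is flagged).

**CC (global cross-correlation).** `compute_cc()` reports the zero-lag
Pearson correlation of the full series (CC-raw) and three monotone
transforms: absolute value, Fisher-Z, and square. The global reading (one
correlation per dyad, not an average of sections) is adopted: it is the only
reading under which the raw and Z columns of a cohort are rank-identical
while raw and abs are not, which is exactly the pattern these four variants
are meant to exhibit.

**rMEA-style WCC/WCLC.** `wclc_matrix()` computes Fisher-Z-transformed
absolute correlations between a 60-s reference window of A and 5-s-lagged
windows of B, stepping the reference by 30 s. `rmea_wcc()` averages the
lag-0 column, `rmea_wclc()` the whole matrix. Lagged windows that leave the
series, and zero-variance windows, are missing and excluded from means.
`person_shuffle_test()` implements the pseudo-synchrony control: each dyad's
A member is re-paired 100 times with the B member of another, uniformly
drawn dyad (with replacement, truncating to the shorter length), and the
real measure is standardized against the surrogate distribution.

**SUSY.** `susy()` cuts the series into non-overlapping 30-s segments and
computes the cross-correlation function over integer-frame lags up to
&plusmn;5 s; a lagged partner window may read into neighbouring frames when
they exist, otherwise the lag is skipped for that segment (this uses the
data symmetrically and keeps real and surrogate pairs on the same footing).
Segment synchrony is the mean over lags of |Z| (Zabs) or signed Z (Znoabs),
and dyad synchrony the mean of segment means. The segment-shuffling
surrogate ensemble is taken exhaustively as all n(n-1) ordered pairs
(A-segment i, B-segment j), i &ne; j, which makes the surrogate stage
deterministic. Effect sizes standardize the real value against the
ensemble: `ES = (Z - mean(Z_surr)) / sd(Z_surr)`.

**SUCO.** `suco()` fits least-squares slopes in 3-s windows stepped by 1 s
inside each 30-s segment, correlates A's and B's slope sequences per
segment (r_i), and aggregates `Z'abs = mean(atanh |r_i|)`. The concordance
index is `CO = ln(sum of positive r_i / |sum of negative r_i|)`, reported
missing when all r_i share a sign (downstream correlation matrices need
finite values, so &plusmn;&infin; is never emitted). ES-abs uses the same
ordered-pair ensemble as SUSY. ES-CO needs a full set of segment
correlations per surrogate, which single pairs cannot provide; the n(n-1)
pairs are therefore grouped into n-1 cyclic-shift surrogate dyads (shift d
pairs A-segment i with B-segment 1 + ((i-1+d) mod n)), each yielding one
surrogate CO. Slope sequences whose spread is at rounding level relative to
their magnitude (e.g. a purely linear trend) are treated as degenerate and
the segment is dropped.

**WCLC-PP / WCLR-PP.** `wclc_rsq_matrix()` stores squared windowed
cross-lagged correlations for every window start (unit increment, b = 125
frames) and lag up to &plusmn;125 frames. `wclr_rsq_matrix()` replaces each
cell by the two-model &Delta;R&sup2;: the follower's lagged window is
regressed on its own window (model 1) and additionally on the partner's
window (model 2), and the cell is `R2_M2 - R2_M1`, the partner's
contribution net of autocorrelation. Design choices here:

* *Lag sign.* A positive lag always means B follows A, in both matrix
  modes, so an injected lag appears at the same signed position everywhere;
  the regression formulation for the opposite direction is the mirrored
  branch. At lag 0 model 1 is saturated and the cell is 0 by construction —
  WCLR cannot assess instantaneous coupling.
* *Significance filter.* Cells failing an F test at &alpha; = 0.001 (df
  (1, b-2) for the correlation, incremental df (1, b-3) for the regression)
  are set to 0; both modes share the filter behind the same `alpha`
  argument (pass `NULL` to disable). Degrees of freedom use the window's b
  observations without an effective-sample-size correction, matching a
  plain R-squared-difference test.
* *&Delta;R&sup2; floor.* Negative increments (suppression) are floored at
  0 because peak picking reads the matrix as a nonnegative strength
  surface.

`peak_picking()` detects per-row local maxima along the lag axis (a maximal
run of equal values qualifies when its flanking values are strictly smaller
or absent; the run is represented by its smallest-|lag| member), chains
same-lag maxima over consecutive rows, resolves row-sharing conflicts by
keeping the interval with the larger mean (the loser is discarded
entirely), and drops intervals with mean &le; 0.25. `sync_frequency()`
reports the proportion of covered reference-window rows by default; a
frame-coverage alternative is available via `convention = "frames"` since
"proportion of the duration" is ambiguous between the two.

**Mutual information.** `mutual_information()` estimates MI from a binned
2-D Gaussian kernel density (Silverman bandwidth per series, 101&times;101
grid); marginals are the grid marginals of the joint, so the plug-in
estimate is a Kullback-Leibler divergence and therefore nonnegative. Bias
is removed by a delete-block jackknife over 50 contiguous blocks
(`B*MI - (B-1)*mean(MI_-b)`), whose standard error yields the Z score. The
block form costs O(B) density estimates instead of O(n); setting
`jackknife_blocks = n` recovers leave-one-out on short series. Units are
nats by default. Exact agreement with any particular MI library is not a
design goal; sign, symmetry, calibration under independence and monotone
ordering in coupling strength are.

**Windowed CRQA.** `wincrqa()` rescales both series to the unit interval,
embeds them (dimension 3, delay 1 frame — the delay is not standard in this
literature and is exposed in `crqa_params()`), and evaluates windows of
1500 frames with 750 overlap. Recurrence is Euclidean distance below
&epsilon; = 0.05, restricted to the diagonal band |i - j| &le; 125, which
parallels the &plusmn;5-s lag range of the other methods (a full-matrix
mode exists via `lag_band = NULL`). RR is the recurrent share of band
cells; DET the share of recurrent points on diagonal runs of length
&ge; 2; ENTR the Shannon entropy of the run-length distribution normalized
by the log of the number of distinct lengths (0 when fewer than 2). DET is
undefined (missing) in windows without recurrent points; window averages
skip unanalyzable windows.

## The synthetic-data generator

No public corpus of interview motion-energy series exists, so the
generator emulates their salient features: non-negative, bounded 0--100,
25 fps, long quiet stretches interrupted by movement episodes, lengths in
the 10k--45k frame range, and episodic lagged linear coupling.

* *Bursts.* Movement episodes arrive as a renewal process with exponential
  gaps calibrated to the target rate, which is Poisson-like but
  non-overlapping by construction. Defaults are 3 bursts per minute of 125
  frames (5 s) at amplitude 20 with unit Gaussian noise and baseline 0.5 —
  roughly 25% movement occupancy, the episodic regime of seated
  conversation. Under these defaults uncoupled members are near-independent
  (mean |global r| well below 0.1), which the coupling machinery requires
  of its null.
* *Coupling.* Inside each scheduled interval the follower copies the
  driver: `B[t + lag] = sign * beta * A[t] + noise`, with an offset keeping
  anti-phase coupling inside the value range. `coupling_noise_sd` can
  differ from the members' own noise, so a noiseless (exact) copy can ride
  on noisy members. The schedule is returned as ground truth.
* *Cohorts.* Groups are allocated exactly; each dyad draws a latent
  coupling strength from its group's Gaussian, receives a random
  non-overlapping interval schedule with that strength, and integer PHQ9-
  and GAD7-like scores truncated to 0--27 / 0--21 are generated from the
  latent coupling (negative slope by default: more symptoms, less
  synchrony). One master seed drives cohort-level draws first, then one
  sub-seed per dyad, so whole cohorts are bit-reproducible.

What the generator does **not** model: realistic human kinematics, camera
noise, nonstationarity of movement style over a session, facial or vocal
channels, or any distributional fidelity beyond the burst-episode
structure. A passing test on synthetic cohorts therefore certifies the
algorithms and their calibration, not claims about real clinical data.
One consequence worth knowing: identically shaped rectangular bursts are
strongly self-similar, so WCLC (which does not remove autocorrelation)
produces short spurious near-perfect intervals on burst-driven dyads;
interval-recovery checks therefore use noise-driven members with an
injected copy, the clean condition for detection claims.

## Validity statistics

`measure_battery()` assembles the 21-column cohort table (failures per
dyad/measure become missing values with logged reasons).
`correlation_matrix()` reports Pearson below and Spearman above the
diagonal with pairwise deletion. `parallel_analysis()` compares observed
correlation eigenvalues against the 95th percentile of eigenvalues from
resampled data; resampling draws each column independently with replacement
(resampling intact rows would preserve the correlation structure and make
the test vacuous), with Gaussian simulation as an alternative. `efa_ml()`
extracts factors by maximum likelihood (`stats::factanal`) and rotates
obliquely with oblimin (direct quartimin), computed by the
gradient-projection algorithm with a deterministic start; RMSR, RMSEA and
TLI are reported (acceptable fit: RMSEA < 0.08, TLI > 0.9), and Heywood
cases are flagged but returned. With 30 dyads and 21 measures the
correlation matrix is singular; the function warns and proceeds, because
that strained regime is precisely the situation such studies face — restrict
`measures` to a subset for stabler fits. `group_comparison()` uses
Kruskal-Wallis tests and Hedges g (pooled SD, small-sample correction
`1 - 3/(4N - 9)`, sign: patient minus control); `symptom_correlations()`
reports Pearson and Spearman coefficients against the symptom scores. No
multiplicity correction is applied by default (unadjusted p < 0.05 stars
are the convention in this literature); a Benjamini-Hochberg adjustment can
be applied to the returned p-values with `p.adjust` if desired.

## Problem sizes and determinism

The test suite checks every windowed quantity against brute-force oracles
(double loops, `lm()`, sort-and-pick-middle) on instances up to ~1000
frames at 1e-10 tolerance, runs calibration nulls with 100--200 replicates
at 1200--1500 frames, and verifies bit-identical reruns of the full
pipeline on a 30-dyad cohort of 15,000-frame series — the scale of a
typical interview study. Everything downstream of the generator is
deterministic given the configuration: surrogate ensembles are exhaustive,
and the only seeded stages are the generator, the person-shuffle pairings,
and parallel-analysis resampling.

## Known limitations

* The minimum-rank factor analysis variant is not implemented (ML only).
* Leading/following decompositions (sign-resolved lag asymmetries of SUSY,
  SUCO and the LOSI) are not computed beyond the signed lag stored per
  interval.
* MI is global; no lagged or windowed MI.
* CRQA embedding delay, minimum diagonal line (2), and the band reading of
  the "maximal lag" are conventional choices where the methods literature
  is silent; all are exposed in `crqa_params()` for sensitivity analyses.
* The generator's burst statistics are plausibility choices, not estimates
  from real recordings.
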