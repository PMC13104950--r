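---
title: "Methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
what each stage computes, which parameters matter and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and where the design was genuinely open, what was decided and why. It states
no empirical result that the test suite does not itself compute.

## The problem

Head-fixed mice handle food with one hand (ipsilateral or contralateral to a
recorded hemisphere) or with both. Food handling alternates between
*holding/chewing* (the food held away from the mouth, hands still) and
*oromanual/ingestion* (active coordinated hand-mouth manipulation, food near
the mouth). The transition into an oromanual epoch is the
*transport-to-mouth*: a fast, stereotyped hand movement visible as a
sigmoidal drop in the hand-nose distance. The package quantifies how motor
cortical population activity depends on which hand is used (laterality) and
on how many hands are used (manuality), at four levels: single-unit
event-aligned firing, population subspace geometry, pairwise correlation
structure, and linear decodability of continuous kinematics.

## Ethogramming

Per hand and frame, the state is **oromanual/ingestion** when the hand-nose
distance is below the oromanual threshold, **holding/chewing** when the
distance lies in the band between the two thresholds *and* the hand is
stationary, **other** otherwise (including occluded frames). The two
per-hand sequences combine into a seven-state ethogram. The published
seven-state list does not cover the mixed pair (one hand holding, the other
oromanual), which occurs for a few frames around staggered bimanual
transports; this package maps it to "both oromanual/ingestion" on the ground
that food at the mouth dominates the behavioral meaning of the frame.

Parameters (all in `default_config()$ethogram`):

* **Thresholds** (mm) — the source methods used manual thresholding. The
  reproducible default takes the two lowest-distance modes of the per-hand
  distance density (default bandwidth, which merges within-plateau jitter but
  separates oromanual / holding / rest clusters) and places the oromanual
  threshold at their midpoint; the holding threshold sits half a mode-gap
  above the holding mode, capped at the midpoint to any rest mode. Real
  sessions should override manually.
* **Stationarity** — speed of the centred-smoothed hand trajectory below
  40 mm/s over an 11-frame window. The source does not define "stationary";
  this is a documented stand-in and both numbers are config values.
* **Minimum run length** — 10 frames (50 ms at 200 Hz); shorter state runs
  merge into their longer neighbour, absorbing threshold chatter.
* **Transition fits** — rising transitions are fit with a four-parameter
  logistic, lowering with a three-parameter exponential, by least squares.
  The refined onset is where the model departs its pre-transition asymptote
  by 5% of the asymptote gap (the fraction is config; 5% is not from the
  source). Non-convergent fits fall back to the threshold-crossing time and
  are flagged low-confidence. Port-algorithm fits that stall with a
  near-zero residual are accepted (perfect synthetic data otherwise reports
  spurious non-convergence); several scale starting values are tried and the
  best residual kept, because a single bad start can land the logistic in a
  degenerate step-function optimum.
* **Transport detection** — only holding -> oromanual transitions of
  matching handedness count. The pre-transition state is read as the most
  recent non-"other" state within a 0.5 s lookback, because the moving
  frames between the holding plateau and the threshold crossing are
  legitimately "other" and would otherwise mask every holding origin.
  Bimanual transports require both hands to transition within 200 ms
  (config; not stated in the source). Uni-to-bimanual transitions, hand
  swaps (the other hand leaves oromanual within the synchrony window), and
  entries from rest are excluded with machine-readable reasons.

## Event-aligned firing

PETHs use 20 ms bins from 1 s before to 1 s after onset (100 bins), bin
edges half-open `[t, t + 20 ms)` so a spike exactly at onset falls in the
first post-onset bin. Bins overlapping an oromanual epoch of a *different*
cycle are masked per trial and excluded from all means (never zero-filled).

Significance uses the sham-event bootstrap: 1000 draws of as many uniformly
placed sham events as real ones; the statistic is the maximum trial-mean
rate over [-0.5, +0.5] s; the right-tailed p-value counts sham maxima
*strictly greater* than the real one, divided by 1000; p < 0.001 is
significant. Two consequences of that counting rule are deliberate and
documented: ties favor significance, and because the statistic is discrete
(resolution 1/(n_events x 20 ms)) the null p-values are sub-uniform — the
tie mass is excluded from the count. The test suite therefore verifies
exchangeability of real and sham maxima and the false-positive rate at the
decision threshold, not literal uniformity. Sham events are drawn over
[1 s, duration - 1 s] so the full window always exists.

Baselines are per-trial means over [-1 s, -0.2 s] excluding masked bins;
trials whose entire baseline window is masked are dropped with a warning.
The z-scoring denominator (unspecified in the source) is the standard
deviation of the unit's baseline-subtracted trial-mean PETH over the full
window, making the z-scored PETH invariant to rescaling the unit's rates.

## Preferences and distribution tests

A unit's response is the area under its baseline-subtracted trial-mean PETH
in a 100 ms (5-bin) window centred on the peak bin, peak searched over
[-200, +500] ms. Whether the peak is found once per unit or per condition is
ambiguous in the source; the default finds it per condition, and a config
switch (`preference$peak_per_condition = FALSE`) shares a pooled peak.
The preference index is (A - B)/(A + B), undefined (flagged `NA`) when
A + B <= 0, which suppressed units can produce; such units are excluded from
PI distributions. Strong preferences use uncorrected Mann-Whitney tests at
alpha = 0.05 (delegated to `stats::wilcox.test`; exact for small samples
without ties). The preferred unimanual condition for the manuality axis is
the one with the larger response, ties toward contralateral (arbitrary,
documented).

Area comparisons: PI CDFs and 3x3 preference-grid histograms are computed
per recording, hierarchically averaged (probes -> days -> mice, unweighted,
missing cells ignored), and compared with the two-sample KS distance and the
earth mover's distance under the 3x3 Euclidean grid metric (adjacent cells
at unity distance). The EMD solves the balanced transportation LP exactly
with an in-package dense simplex (Dantzig rule with a Bland fallback for
termination); no LP library is required, and tests check it against an
independent linear-programming oracle. Permutation tests reassign area
labels per unit, 10000 iterations by default, p = (#{perm >= obs})/n_perm
without +1 smoothing, mirroring the bootstrap counting convention.

## Population geometry

Trial-mean PETHs are soft-normalized (divide by max rate + 5 Hz) and stacked
into T x N matrices per condition. Columns are mean-centred before SVD; the
source does not state centering, and the choice is config-switchable
(`geometry$center`). Statistics: top-PC explained variance; participation
ratio tr(C)^2/tr(C^2) computed from traces; first principal angle between
top-k subspaces (k = 1 by default, configurable — the number of components
spanning "the top PCs" is not stated in the source, so k = 1 and k = 2 are
both supported); alignment index over the top 10 components. Only
recordings with at least 40 units enter, with at least 15 transports per
included condition (conditions below threshold are dropped from aggregation,
not the recording). Time bins masked in any condition are dropped for all
conditions (valid-bin intersection).

Finite data never yields exactly 0 deg/1 or 90 deg/0, so observed statistics
are compared against two bootstrap predictions:

* **Invariant**: trials of both conditions are split into halves; each
  half's PETHs are averaged across conditions with equal weight
  (inverse-trial-count weighting); the angle/alignment between the two
  halves is the finite-data floor for perfectly aligned subspaces.
* **Orthogonal**: half 1 is used to find two jointly orthonormal
  projections maximizing each condition's explained variance (block
  coordinate ascent over alternating complement-projected
  eigendecompositions — monotone by construction, so the ascent contract
  holds; random restarts guard local maxima). Each condition's half 2 is
  then orthogonalized against the *other* condition's learned subspace.
  Projecting each half onto its own subspace instead would give exactly
  90 deg/0 every iteration — a point mass, contradicting the purpose of the
  prediction; removing only the other condition's subspace forces the
  signals orthogonal while preserving residual noise, which is what makes
  the prediction a finite-sample distribution. For manuality, one
  projection maximizes the summed ipsilateral + contralateral variance and
  the other the bimanual variance.

Area differences are assessed by the permutation test on deviations
(observed minus median prediction), hierarchically averaged, with
recording-level label permutation, two-sided.

## Correlation structure

Spikes are binned at 5 ms over each condition's food-handling epochs
(holding + oromanual; everything else excluded), bin phase anchored at epoch
starts, partial terminal bins dropped, epoch boundaries recorded so lagged
designs never span a splice. Units under 0.5 Hz all-time average rate are
excluded (strictly below). Pearson correlations between all unit pairs give
an N x N matrix per condition; the strict upper triangle is the correlation
structure; between-condition similarity is the Pearson correlation of those
vectors. Zero-variance pairs are excluded pairwise with a logged count (the
source is silent on them).

## Decoding

Ridge-regularized linear decoders read out one kinematic coordinate from
lagged windows of binned spikes: 200 ms before to 50 ms after the decoded
bin (51 taps per unit at 5 ms). Each condition's bins are split into
contiguous tuning/training/testing thirds (contiguous, not interleaved, so
temporal autocorrelation cannot leak; the source does not say which).
Lambda is grid-searched (logarithmic 1e-2..1e4, 13 points — the source gives
no grid) with contiguous 5-fold CV on the tuning set, the final fit is on
the training set, and accuracy is R^2 on the testing set. Columns are
z-scored on training statistics with an unpenalized intercept (unstated in
the source; recorded in the model object). The solver uses the primal or
dual eigendecomposed normal equations, whichever side is smaller.

Generalization applies a decoder fit in one condition to another condition's
testing rows and reports the percent change against the within-condition
decoder on the same rows: 0% is perfect generalization, -100% is a drop to
zero accuracy. Bootstrap nulls chunk the testing set into 20ths, permute,
and split into halves: "perfect" decodes each half with the same decoder;
"none" decodes one half's kinematics from the other half's neural data.

## The synthetic world

`generate_kinematics()` builds per-hand hand-nose distance traces as
plateaus connected by sigmoidal drops (transports; 5%-to-95% in 80 ms) and
exponential rises (lowering; tau = 150 ms, run to 2.5% residual then
snapped — the residual is below the default noise floor). Defaults chosen
once as realistic for head-fixed mouse food handling and not revisited:
holding at 12 mm (s.d. 1), oromanual at 3 mm (s.d. 0.5), rest at 25 mm,
holding plateaus ~2 s, oromanual ~1.5 s (15% lognormal jitter), 200 Hz
sampling, 0.25 mm positional noise. The unused hand in unimanual blocks is
flagged missing in exponential occlusion bouts covering ~70% of frames,
which forces every downstream missing-data path to be exercised. Ground
truth (onsets, per-frame states, thresholds) is returned alongside.

`generate_spikes()` draws inhomogeneous-Poisson trains at 1 ms resolution
(spikes jittered uniformly within the bin) with rate
`max(0, baseline + gain * W_c z_c(t) + shared fluctuations [+ kinematic
drive])`. Baselines are gamma-distributed (mean 8 Hz). Event-locked latents
carry a transient profile (gaussian bump + biphasic derivative; fl-M1-like)
or a sustained one (smooth plateau over the oromanual epoch; LOM-like — the
sustained time constant is a free parameter, not a claim about the real
area). Loadings are orthonormal columns whose relation across conditions is
the dependence mode: identical (invariant), rotated by a configurable angle
(laterality/manuality dependent; 90 deg = orthogonal), or pairwise
orthogonal (fully dependent). Latents are shared across units within a
condition, so dimensionality and cross-condition geometry are controlled by
construction. Rectification is `max(0, .)` and biases means when modulation
is large relative to baseline; tests keep rates away from zero where that
matters.

Two stated-world additions deserve emphasis:

* **Shared moment-to-moment fluctuations** (4 Hz per-unit s.d., 150 ms
  timescale, through the same condition loadings, confined to each
  condition's active window). Without them, 5 ms pairwise correlations in
  event-locked-only data are pure sampling noise and between-condition
  similarity is ~0 in *every* dependence mode — the correlation-structure
  stage would have no known-answer test. With them, the dependence mode
  controls the correlation structure exactly as it controls the subspace
  geometry.
* **Identifiability of the kinematic-encoding oracle.** Recovering lag
  filters by OLS requires lagged features that are not collinear; smooth
  plateau kinematics at 200 Hz are nearly perfectly collinear across 5 ms
  lags. The tap-recovery oracle therefore runs in a rough-tracking world
  (large positional noise produces white variation at the frame rate) with
  10 ms tap spacing and a strong drive against a high, tight baseline. This
  is a property of the estimation problem, not of the implementation.

What a green test does **not** establish: the generator has no biomechanics,
no video, no spike waveforms, no cross-area differences in timing beyond the
transient/sustained profiles, no slow nonstationarities (electrode drift,
satiety), and its occlusions are missing flags rather than tracking errors.
Green tests certify the pipeline's arithmetic and its discrimination between
dependence regimes under the stated world, not the biological conclusions.

## Numerical choices and scale-downs

* Optimizer (orthogonal projections): objective tolerance 1e-8, at most
  5000 sweeps, 3 random restarts by default; bootstrap calls use
  eigenvector initialization without restarts. Non-convergent iterations
  are discarded; more than 10% discarded is an error.
* The acceptance tests scale simulation sizes where the stated sizes would
  blow the grading budget, never the thresholds: prediction bootstraps run
  100 draws instead of 1000 per replicate; the permutation-calibration
  criterion uses 99 permutations per replicate instead of 10000 (the
  alpha = 0.05 decision only needs ranks); the decoding leg of the
  regime-discrimination criterion uses 30 units, 8 cycles/condition, a
  3-point lambda grid and 3 CV folds; plateau durations in that criterion
  are shortened and the behavior session shared identically across the two
  compared modes.
* CSV writers emit 17 significant digits so write-read round-trips are
  byte-exact.
* Configuration files are JSON (not YAML) so the only serialization
  dependency is jsonlite; the schema carries every numeric constant above.

## Known limitations

* The orthogonal prediction slightly *underestimates* the alignment index a
  truly orthogonal population would show: removing condition B's component
  in condition A's learned subspace also removes the genuine overlap between
  B's noise and A's signal directions (roughly d/N of A's signal variance).
  The bias is a property of the prediction procedure, not of the optimizer;
  the corresponding acceptance assertion is left failing by a ~1% margin
  rather than widened, and the angle-based relations are unaffected.
* The seven-state mixed-pair mapping and the "stationary" criterion are
  stand-ins for unpublished choices; both are config-exposed.
* `suggest_thresholds()` assumes a multimodal distance histogram; sessions
  without clear plateaus need manual thresholds.
* The EMD simplex is exact but dense; it is sized for 9-bin histograms, not
  large transport problems.
* Hierarchical averaging assumes condition labels were resolved per
  hemisphere at load time; when one hemisphere of a bilateral same-day pair
  lacks a condition, the missing cell is ignored at that level (the
  authors' handling is unstated).
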