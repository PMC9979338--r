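---
title: "Detecting a brief mindfulness effect in resting-state EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a brief mindfulness effect in resting-state EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mfrest)
```

## The question and the design

A two-minute guided breathing meditation is a very small intervention, and
any trace it leaves in the EEG is expected to be small relative to
between-epoch variability.  The design this package implements therefore
works *within* participants: four resting-state recordings are taken in
task order — TaskRest1 (2 min), Pre-MF (1 min, immediately before the
meditation), Post-MF (1 min, immediately after) and TaskRest2 (1 min) —
and a participant-specific classifier is asked to separate Pre-MF from
Post-MF one-second epochs.  The two flanking rests, which are separated
from the Pre/Post pair by card-game blocks rather than meditation, act as
temporal-drift controls: if the classifier has merely learned "later in
the session", the separation between Pre-MF and Post-MF scores should be
no larger than between TaskRest1 and Pre-MF or between Post-MF and
TaskRest2.

The pipeline is: artifact cleaning to 1-s epochs → seven Welch band-power
features on 19 channels (133 candidates) → per-participant z-scoring →
greedy forward selection of (channel, feature) pairs under a
class-balanced cross-validated cost → RBF-SVM evaluation over Monte-Carlo
cross-validation → kernel density estimates of the decision scores →
symmetric Kullback–Leibler distances between consecutive states →
normalized contrasts `Distance1 = (D23 − D12)/(D12 + D23)` and
`Distance2 = (D23 − D34)/(D23 + D34)` summarized across the cohort as
`P(Distance > 0)`.

## Spectral features

Per epoch and channel: total 4–30 Hz power; absolute theta (4–7 Hz),
alpha (8–12 Hz) and beta (16–30 Hz) power; and the three relative powers
(band / total).  The 7–8 and 12–16 Hz gaps belong to the total only and
are deliberately not re-assigned to a band.  Welch parameters are a
package choice (the method itself fixes only the periodogram): 0.5-s
Hamming segments with 50% overlap give three segments per 1-s epoch and a
2 Hz grid at 300 Hz — a reasonable variance/resolution trade-off at this
epoch length.  Two consequences worth knowing: band integrals use
trapezoids over bin centres inside the closed band, and a pure sinusoid's
relative band power saturates near ~0.85 rather than 1 because the
Hamming mainlobe leaks into the two adjacent bins.

One channel-list note: the published feature-channel list contains a bare
"T" label; the package reads it as T4, the only 10–20 temporal site
missing from the list.  Pz doubles as the site-1 hardware reference yet
appears in the feature list; the printed list wins.

## Cleaning chain

Fixed order: resample to 300 Hz → zero-phase Kaiser FIR band-pass
(1–30 Hz) → bad-channel detection → subspace reconstruction → segment
rejection → A1/A2 re-reference → 1-s epoching → spherical-spline
interpolation of removed channels.  Parameters, with the method's values
as defaults:

* **Band-pass.**  Only the cut-offs are prescribed; the package designs
  for 60 dB stopband attenuation and a 1 Hz transition width
  (Kaiser beta ≈ 5.65, order ≈ 1100 at 300 Hz) and applies the
  linear-phase filter with group-delay compensation.  Note the impulse
  response spans ±1.8 s: a flat interval must exceed the 5-s rule by
  roughly the filter length to survive filtering, which matters when
  constructing fixtures.
* **Bad channels.**  (a) any contiguous ≥5 s with peak-to-peak below
  10⁻⁶ µV ("no signal"); (b) line-noise ratio — power within ±2.5 Hz of
  50/60 Hz over total power — more than 4 standard deviations above the
  across-channel mean.  The population over which the z-score is taken is
  not stated in the source description; across channels is the
  interpretation used, and with 21 channels a single extreme channel can
  reach z ≈ 4.36, so the rule is attainable but deliberately
  conservative.
* **Subspace reconstruction.**  A simplified artifact subspace
  reconstruction: calibration statistics come from the cleanest 50% of
  0.5-s windows by RMS; each window is decomposed into its own principal
  components, and any component whose standard deviation exceeds 30× the
  calibration data's standard deviation along that direction is zeroed
  (iterated up to five times per window, since removing a dominant
  artifact component can expose a mixed direction just under threshold).
  Clean data passes through bit-identically because no component trips.
  A caveat of the fixed 30× cutoff: a high-rank artifact (say, a burst
  spanning six channels) spreads its sample eigenvalues widely within a
  0.5-s window, and its smallest component can sit just *below* 30× even
  when the burst is ×50 — such bursts are instead caught by segment
  rejection, which is the stage the design pairs them with.
* **Segment rejection.**  1-s windows whose log-power is more than 20
  robust standard deviations (median/MAD across windows, per channel)
  above typical power in at least ⌈25%⌉ of channels are removed.  The
  robust scale is a deliberate numerical choice: a moment z-score over W
  windows is algebraically bounded by (W−1)/√W ≈ 7.6 at W = 60, so a
  20-SD rule could never fire with a plain z.
* **Re-reference.**  Mean of A1/A2 subtracted everywhere; if either ear
  channel is missing or bad the chain falls back to a common average
  reference with a logged warning.
* **Interpolation.**  Spherical splines (order m = 4, 7 Legendre terms,
  ridge 10⁻⁵) on standard unit-sphere 10–20 positions — the standard
  published defaults.
* **Component pruning.**  The classifier-based independent-component
  pruning used with real recordings depends on a pretrained network and
  is out of scope; an optional kurtosis-thresholded principal-component
  pass is available and off by default.

Every rejection is logged with rule, location and threshold, and all
thresholds are fields of `mf_config()`.

## Statistics

`rank_sum()` implements the two-sided Wilcoxon rank-sum test with midrank
ties: exact enumeration of the rank-sum null over all C(n, n1)
assignments when n ≤ 10, and the tie-corrected normal approximation with
continuity correction otherwise.  Tests verify the exact branch against
brute-force enumeration and both branches against `stats::wilcox.test`.
State-pair tables pool *epoch-level* channel- or region-averaged values
across participants (the alternative unit, participant means, is
available via `unit = "participant"`); no multiple-testing correction is
applied, matching the per-cell 0.05 reporting convention of the design,
and this is recorded in the table's metadata.

## Selection and classification

The forward selection is bottom-up: starting empty, every remaining
(channel, feature) pair is scored by the cross-validated cost of the
candidate set with that pair added, and the argmax joins the set.  The
cost is `mean accuracy − λ·|sensitivity − specificity|` averaged over
seeded Monte-Carlo repetitions of stratified k-fold cross-validation;
λ = 0.5 penalizes class imbalance at half weight so accuracy still
dominates — the balance *goal* is prescribed, its functional form is this
package's interpretation.  Stopping: best improvement < 0.001, or 20
pairs (defaults; the source gives neither).  Ties break to the lowest
pool index.  The SVM uses an RBF kernel with fixed hyperparameters
(cost 1, kernel width 1/(d · overall feature variance)); no inner search
is performed because none is described.

Evaluation runs 100 Monte-Carlo repetitions of stratified 5-fold
cross-validation; out-of-fold decision scores are averaged over the
ensemble, and the same frozen ensemble — no retraining — scores the
TaskRest1 and TaskRest2 epochs.  Whether the headline metrics belong to
the 10-fold selection stage or the 5-fold evaluation stage is ambiguous
in the source; this package reports the evaluation stage.  Pre-MF is the
positive class everywhere.

Greedy selection over 133 candidates is a powerful overfitting engine: on
a pure-noise participant the best of 133 noisy cross-validated costs is
far above chance, and any quantity computed from the same epochs inherits
that bias.  `mf_fit()` therefore applies a hygiene split: the forward
selection sees only a seeded half of the Pre/Post epochs.  The reported
metrics remain the Monte-Carlo cross-validated rates over *all* epochs
(the convention of the original design), but the score samples passed to
the density validation are restricted to the untouched half, and the
flanking states are scored with one fold model per epoch per run — the
same variance structure as the out-of-fold Pre/Post scores — so that
under an exchangeable null all four score distributions are actually
exchangeable.  Without this split the null probabilities `P(Distance>0)`
are badly miscalibrated (anywhere between ~0.25 and ~0.95 depending on
how the flanking scores are averaged).

A held-out variant (`heldout_accuracy()`) splits each class's epochs in
half, confines selection *and* training to one half and measures accuracy
on the other: on a null participant this is an unbiased chance-level
check, guarding against the selection bias that inflates the in-sample
path.

## Validation

Scores of all four states are density-estimated on one shared grid (512
points spanning the pooled range padded by three bandwidths; Silverman's
rule per state) — a shared grid is required for the distance to be
well-defined.  Densities are floored at 10⁻¹² and renormalized so the KL
log terms stay finite; this floor is a numerical regularization, not part
of the method.  The symmetric KL distance is computed in natural log
(nats) over trapezoid grid masses; the summation domain (grid versus raw
scores) is implicit in the source, and the KDE grid is used.  Cohort
summaries are 20-bin normalized histograms of Distance1 and Distance2 on
[−1, 1] and the fractions of participants above zero.

One calibration property worth stating precisely: under the
*exchangeable* null — all four states drawn from identical generative
distributions — the contrasts are symmetric and `P(Distance > 0)` sits at
one half (measured 0.55/0.57 over six 10-participant simulated cohorts,
consistent with 0.5).  Under a null with session drift but no meditation
effect, Pre-MF and Post-MF genuinely differ, the classifier is trained on
exactly that pair and amplifies its separation more than the equally
drifted flanking transitions (whose scores sit in the RBF's saturating
region), so the probabilities land mildly above one half (~0.65 at a
+0.05 log-gain drift per transition).  The validation is thus slightly
anticonservative against pure drift — an inherent property of validating
with the same classifier that was trained on the contrast of interest,
and worth remembering when reading cohort probabilities close to 0.5.

## The synthetic cohort generator

No recordings are deposited with the source study, so the package ships a
seeded generator that *defines* the study conditions for all tests.  Each
channel is a sum of band-limited Gaussian oscillations (white noise
masked to the band in the Fourier domain — flat within-band spectra, not
line spectra) plus 1/f pink noise; baseline RMS amplitudes are
theta 3 µV, alpha 4 µV, beta 2 µV, pink 5 µV, values a practitioner
would call plausible awake eyes-open rest.  Alpha is weighted ×1.5
occipitally and beta ×1.3 frontally so that channel selection has
something real to find.  The four states implement the published
band-power trajectory directions: a +0.05 log-gain drift on all bands per
no-meditation transition (the no-MF transitions in the source are
significant, so drift must be nonzero), an alpha +δ / beta −δ log-gain
shift at Post-MF, and retention of half the meditation effect at
TaskRest2 (the partial rebound).  δ is a calibration choice — the source
reports directions and p-values, not magnitudes — fixed at 0.3 for the
effect condition and 0 for the null.

What the generator does **not** emulate: eye blinks and other
physiologically shaped artifacts, ERP structure, cross-channel source
correlation, non-stationarity beyond the state gains.  Passing tests
therefore demonstrate the pipeline's logic and calibration under its own
stated assumptions, not performance on real paediatric EEG.

## Problem sizes and determinism

Study-scale defaults are 10-fold × 5-MC selection (cap 20) and
5-fold × 100-MC evaluation with the full durations (120/60/60/60 s).  The
test suite and the acceptance script run the documented `fast` profile
(5-fold × 2-MC selection, cap 8; 5-fold × 10-MC evaluation) on n = 10
cohorts, and the 20-seed null replication of the validation probabilities
uses 30-s states with a further reduced Monte-Carlo profile — the null
symmetry being checked is invariant to recording length, and these sizes
keep a full run on one core in minutes.  Every stochastic stage takes a
seed; equal seeds reproduce cohorts, fits and reports byte-identically.

## Worked example

```{r example}
cohort <- simulate_cohort(4, delta = 0.3, seed = 1)
run <- mf_run(cohort, mf_config("fast", seed = 1))
summary(run)
plot(run)
```

## Known limitations

* The simplified subspace reconstruction is not the published ASR
  algorithm (no RMS-threshold calibration statistics, no sliding-window
  blending); it is a documented approximation with the same rejection
  rule.
* The λ-penalized cost is one reading of "weighted" selection; the
  original weighting scheme lives in a citation the source does not
  reproduce.
* Epoch-level pooling treats epochs as exchangeable across participants
  in the rank-sum tables; participant-mean pooling is available but not
  the default.
* Real-data ingestion is limited to the package's plain-text container;
  EDF readers exist in other toolchains and can be bridged through it.
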