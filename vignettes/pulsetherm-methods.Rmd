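---
title: "pulsetherm: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pulsetherm: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pulsetherm implements a remote-physiology analysis pipeline: pulse and
heart-rate-variability (HRV) extraction from multi-region facial RGB
traces, segment-wise facial temperature features, and multimodal fusion
classifiers with Shapley-value feature attribution. This vignette is the
package's own account of the models it implements, the defaults it ships,
and the choices made where the design was genuinely open.

## The measurement model

The package starts from *traces*, not video: per-region mean colour
intensities (`time_s, roi_id, R, G, B`) at a known frame rate, and
per-region facial temperatures (`time_s, roi_id, temp_c`) for 22 defined
regions. Face detection, landmark tracking and radiometric calibration are
upstream concerns and out of scope. The physiological premise is standard:
cardiac pulsation modulates skin colour by a fraction of a percent through
haemoglobin absorption, and autonomic activity shifts regional facial
temperature on a scale of tenths of a degree over minutes.

## Pulse extraction (POS)

For each region, every sliding window of `pos_window_s = 1.6` s (hop of
one sample) is processed as follows: each channel is divided by its window
mean — *temporal normalisation*, which makes the output exactly invariant
to per-channel multiplicative gain — then projected with the fixed matrix
rows $(0, 1, -1)$ and $(-2, 1, 1)$ to two signals $S_1, S_2$, combined as
$h = S_1 + \tfrac{\sigma(S_1)}{\sigma(S_2)} S_2$ (population standard
deviations within the window), mean-centred and overlap-added. The 1.6-s
window is the convention of the method's original formulation; it spans at
least one cardiac cycle at 39 BPM while keeping the skin-tone axis locally
constant. Degenerate windows with $\sigma(S_2) = 0$ (e.g. constant input)
contribute $S_1$ alone, which makes a constant trace map to an exactly
zero pulse.

## Windowed spectral heart rate

The pulse waveform is segmented into 6-s windows with a 1-s hop
("overlapping windows" fixes only the first number; the hop is our
default). Each window is mean-removed and zero-padded so the discrete
frequency grid is no coarser than 0.25 BPM — zero-padding is preferred to
parabolic peak interpolation because it is bit-exactly specifiable. The
heart rate is 60 times the argmax of the magnitude spectrum within the
physiologic search band 0.65–4.0 Hz (39–240 BPM, configurable). Windows of
exact zeros yield missing estimates; windows whose in-band peak is less
than half the global spectral peak are flagged `low_confidence`, which is
what happens when the true dominant frequency lies outside the band.

Per-window aggregation across regions uses the **median**: single corrupt
patches then shift the aggregate little, which is precisely the failure
mode the MAE/HR index quantifies. The index divides the mean absolute
deviation of per-region window HR from the aggregate by the *global* mean
aggregate HR (a per-window normalisation would be equally defensible; the
global form is declared and tested). It is zero iff every region agrees
with the aggregate everywhere, and scale-free.

## HR cleaning and HRV measures

The jump filter scans left to right and, wherever successive points differ
by more than 25 BPM, deletes whichever of the pair lies farther from the
median of the *full input* series, ties deleting the current point. Passes
repeat until stable, so the filter is idempotent and its output is a
subsequence of its input; the median is kept fixed across passes so the
reference does not drift as points are removed.

NN intervals are `60000 / HR` ms at the window timestamps, bounded to
300–2000 ms (the image of the HR search band; out-of-range values are
conversion artifacts and are dropped with a count). Time-domain measures
follow their textbook definitions: SDNN with the $n-1$ denominator
(declared, for bit-exact tests), rMSSD as the root mean square of
successive differences, pNN50 with a *strict* > 50 ms inequality.

Frequency-domain measures resample the NN tachogram at 4 Hz by cubic
spline, remove the mean, and estimate the PSD with Welch's method
(Hann-windowed 64-s segments, 50% overlap — no Welch routine ships with
the installed R stack, so `welch_psd()` is implemented in-package and
cross-checked in tests against `stats::spec.pgram` and a closed-form
sinusoid power calculation). LF is the 0.04–0.15 Hz band integral, HF
0.15–0.40 Hz, in ms²; natural logs are reported because band powers are
right-skewed. ULF and VLF are deliberately absent — they are undefined on
the 120-s segments this pipeline analyses.

One deliberate relaxation: the frequency analysis requires a minimum
tachogram span of 100 s rather than a literal 120 s. HR window centres
inside a 120-s segment span at most `segment_s - win_s` seconds (114 s at
the defaults), so a literal 120-s requirement would exclude the 120-s
segment design itself.

Segments are non-overlapping; the *last* segment is anchored to the end of
the recording (`[T - 120, T]`), matching the first-vs-last-two-minutes
change design, and deltas are always last minus first.

## Thermal features

Per region: means of available frames over the first and last 120 s
(windows with under 50% of expected frames are missing — the detector
dropout threshold is ours, stated and configurable), absolute change
(last − first), forehead-referenced change, and the pairwise differential
matrix $M_{ij} = \Delta_j - \Delta_i$ (row subtracted from column), which
is antisymmetric with zero diagonal by construction. The forehead (region
58) is the reference because it is among the most temperature-stable
facial areas; subtracting it cancels any drift common to the whole face
exactly, which the simulator's programmed-drift tests verify to float
precision.

## Fusion and attribution

Records are subject-states (baseline = first 120-s segment, stimulus =
last); this operationalisation of "mental-state change" is a declared
design choice, and any externally supplied binary label works the same
way. Evaluation is stratified k-fold **at subject level** (both records of
a subject share a fold — otherwise a classifier can match records of the
same person rather than detect states). Inside every training fold:
features are z-scored with training statistics only, and hyperparameters
are grid-searched by an inner 3-fold grouped CV (SVM: RBF kernel,
$C \in \{0.1, 1, 10, 100\}$, $\gamma \in \{1/(p \cdot \mathrm{var}(X)),
0.01, 0.1, 1\}$; random forest: 100/300 trees, depth unrestricted/3/5 via
a node cap, minimum leaf 1/3). These grids are declared defaults. The
permuted-label control in the acceptance suite verifies the pipeline sits
at chance when the labels carry no signal — the standard leakage check.

Early fusion concatenates both modalities' features before training. Late
fusion fits one model per modality per fold, obtains *cross-fitted*
class probabilities on the training rows (inner 3-fold, so the
second-stage learner never sees resubstitution scores), and trains a
Gini-criterion decision tree of depth ≤ 2 on the two probabilities.
Probabilities rather than hard votes preserve each base model's
confidence. Feature columns are consumed in sorted order everywhere, so
results are invariant to column permutations.

Feature importance uses Monte-Carlo permutation-sampling Shapley values
(the Štrumbelj–Kononenko estimator) on the positive-class probability
scale, applied identically to SVM and random-forest models. A tree-exact
algorithm would be preferable for forests in principle; the sampling
estimator was chosen because it is model-agnostic, a few dozen lines of
auditable code, fully seeded — and it shares the key exactness property
the tests rely on: a feature the model's prediction function ignores
receives *exactly* zero attribution, since every marginal contribution is
zero. All perturbed rows are scored in one batched prediction call.

The quality sweep filters recordings by MAE/HR threshold and reports
Pearson r (and p) between pipeline-derived and reference-derived measures,
with retained n; thresholds keeping fewer than 3 recordings are marked
insufficient. The correlation map reports raw p-values with a p < 0.05
mask by default — mirroring the exploratory heat-map convention — with an
optional Benjamini–Hochberg mask for confirmatory use. Change t-tests are
one-sample two-sided tests of per-subject deltas against zero;
zero-variance columns are undefined and reported missing rather than
fabricated.

## The synthetic generators

The simulators define the study conditions under which the pipeline is
validated:

* **Beat series** are built by direct NN-sequence construction (not
  integral pulse-frequency modulation — transparency wins, and only the
  spectral content matters downstream): $NN(t) = 60/\mathrm{HR} +
  a_{LF}\sin(2\pi \cdot 0.095 t) + a_{HF}\sin(2\pi \cdot 0.275 t) +
  \varepsilon$. The modulation frequencies are the LF/HF band centres, so
  programmed power lands unambiguously in one band; parameter sets whose
  deterministic minimum NN falls below 0.3 s are rejected, and sampled
  intervals are clamped to 0.3–2.0 s.
* **RGB traces** embed a unit-peak pulse (one asymmetric Gaussian per
  beat — fast rise, slow decay; real waveform shape is unspecified
  upstream and irrelevant to spectral HR), channel-weighted with green
  strongest, plus a slow common illumination drift and white noise, all
  multiplicative on a per-region baseline. Defaults: 2% green-channel
  pulse amplitude, 0.3% noise, 1% drift — strong enough to be realistic,
  weak enough that extraction is non-trivial.
* **Thermal traces** place a linear ramp per region sized so the
  last-minus-first 120-s means equal the programmed group effect, plus
  common drift, AR(1) noise ($\phi = 0.6$) and random frame dropout, at
  8 fps (thermal cameras run slower than RGB).
* **Labeled studies** draw record-level feature vectors parametrically
  (subject random effect + state shift + record noise); the stimulus state
  raises HR, lowers all HRV measures and warms condition-specific regions
  (lips/cheeks under cognitive load; nose, nostrils, lips, cheeks and chin
  under moral elevation), with magnitudes on the order of the
  within-record noise so neither modality is trivially separable. The
  signal chain itself is exercised end-to-end elsewhere; generating
  study-level features parametrically keeps classifier validation
  independent of extraction error and fast.

What the simulators do **not** model: motion and occlusion beyond a common
drift term, ballistocardiographic artifacts, illumination colour changes,
detector-specific thermal noise, or inter-feature correlation structure
beyond the subject random effect. Passing tests therefore demonstrate
algorithmic correctness and statistical calibration under the programmed
conditions, not field performance on real recordings.

## Problem sizes and numerical notes

The shipped test and acceptance runs use 5-minute recordings at 30 fps
with 3 regions, 50 beat-series simulations for band recovery, 1000 fuzzed
series for the filter contract, 10-seed studies of 60 subjects (120
records) for fusion, and 1000 null replicates for t-test calibration —
sizes chosen so each property is measured with comfortable margin while a
full run stays in the minutes range on one CPU. All randomness derives
from explicit integer seeds via a single splitting helper, so every result
in the README and test suite is bit-reproducible. Ties in the spectral
argmax resolve to the lower frequency (`which.max`); ties in the jump
filter delete the current point; grid-search ties keep the first
configuration in grid order.

## Known limitations

* Windowed spectral HR inherently smooths beat-to-beat variability, so
  absolute SDNN/rMSSD values from the r-PPG path underestimate
  tachogram-level variability; segment *changes* are less affected.
* The MAE/HR index measures internal consistency across regions, not
  agreement with ground truth; a systematically biased extraction could in
  principle be consistent.
* The sampling Shapley estimator carries Monte-Carlo error; ranks of
  near-tied features are unstable at small `nsim` (importance magnitudes
  converge as `nsim` grows).
* Late fusion with depth-2 trees on two probabilities is deliberately
  simple; it cannot model interactions richer than threshold agreement.
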