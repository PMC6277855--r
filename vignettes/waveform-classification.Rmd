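---
title: "Classifying cortical neuron types from spike waveforms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cortical neuron types from spike waveforms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(spiketype)
```

## The model

`spiketype` implements a semi-supervised minimum-distance classifier for
neuron types based purely on the shape of individual action potentials
(APs) in intracellular membrane-potential recordings. The underlying
biology: fast-spiking parvalbumin (PV) interneurons fire brief APs with
deep afterhyperpolarizations (AHPs), pyramidal (Pyr) cells fire broad APs
with shallow AHPs, and somatostatin (SST) cells sit in between. Those
differences are stereotyped enough that a single spike carries
substantial information about the identity of the cell that fired it.

The classifier itself is deliberately simple:

* spike epochs are summarized by a feature vector (discrete cosine
  transform coefficients by default, or seven AP morphometrics);
* features are standardized and reduced by correlation-matrix PCA;
* fuzzy c-means (FCM) summarizes each labeled class of the training
  scores by a small number of cluster centers;
* a spike is assigned the class of its Euclidean-nearest center, and a
  neuron the majority class of its spikes.

The semi-supervision lives in step three: class labels are used only to
partition the training data; the within-class structure (e.g. an SST
population that splits into two waveform modes) is discovered by
unsupervised clustering, and the resulting centers — not per-spike
exemplars — are the whole of the trained model. This makes the model tiny
(a few points in PC space), interpretable, and cheap to apply.

Assumptions worth keeping in mind: epochs must contain exactly one AP
each, aligned on the peak; classes are assumed to differ in waveform
shape, not in firing statistics (inter-spike intervals are deliberately
not used); and the Euclidean metric in PC-score space treats retained
components on their natural (variance-weighted) scale.

## Stages and their tunable parameters

**Denoising.** A zero-phase notch (center 50 Hz, bandwidth 5 Hz, design
order 3) removes line interference, then a 0.4 ms moving average smooths
residual broadband noise. The notch is applied forward and backward, so
the net phase shift is zero and spike peak times are not displaced —
essential, since all later stages key on the peak sample. Both stages can
be disabled (`preprocess_trace(notch =, smooth =)`); 60 Hz mains users
should set `center_hz = 60`.

**Detection.** `detect_peaks()` places one marker at the maximum of each
contiguous supra-threshold excursion. The threshold (default −20 mV) is
absolute: AP peaks overshoot toward 0 mV while subthreshold activity
stays near rest (≈ −65 mV), so a wide band of values works; the default
is exposed rather than estimated. `min_isi_ms` (default 2 ms) suppresses
double detections within one AP; it is shorter than any plausible
inter-spike interval and longer than any AP width.

**Epochs.** Windows run from 1 ms before to 2 ms after the peak, as the
half-open sample range `[t − round(pre·fs/1000), t + round(post·fs/1000))`.
At 20 kHz that is exactly 60 samples with the peak at zero-based offset
20. The half-open convention is deliberate: an inclusive reading of
"−1 to +2 ms" would give 61 samples and break the equally standard
"60 samples per epoch" arithmetic, so one endpoint has to go; dropping
the trailing sample preserves the pre-peak alignment.

**DCT features.** Epochs are zero-padded at the tail to 100 samples and
transformed by the DCT-II. Padding at the tail (not symmetrically) keeps
the pre-peak samples at fixed coefficients across epochs. No baseline is
subtracted before the transform: resting/threshold-level differences
between cell types are themselves informative, and the DC coefficient
carries them. Two normalizations are available because the α(k)
convention in this corner of the literature is not settled:
`alpha = "ortho"` (the default; the transform is orthogonal and satisfies
Parseval's identity) and `alpha = "literal"` with α(k) = √((k+1)/N),
which progressively amplifies higher-order coefficients. The two agree
for k ≤ 1, so closed-form checks (a constant input maps entirely to
v(0)) hold for both.

**AP morphometrics.** The seven variables are defined operationally, and
every threshold in the definitions is a parameter:

* APT (mV): voltage at the first pre-peak sample where dV/dt (central
  differences × fs) reaches `dvdt_threshold_v_per_s` (default 10 V/s,
  the common convention for AP onset);
* amplitude A = V_peak − APT (internal, not reported);
* APD (ms): full width at the level APT + A/2, crossings located by
  linear interpolation between samples;
* AHP (mV): APT minus the post-peak minimum, floored at 0;
* rise/fall times (ms): 10 %→90 % and 90 %→10 % of A;
* rise/fall rates (V/s): extrema of dV/dt.

A spike on which a definition fails (no dV/dt crossing, no level
crossing) is dropped with a warning; `$kept_rows` records the surviving
row indices so correctness vectors can be paired across feature kinds.

**PCA.** Standardization uses the training mean and standard deviation of
each column; the correlation matrix is eigendecomposed and the smallest
number of components reaching `cpv` (default 0.90) cumulative explained
variance is retained. The CPV rule is a rule, not a constant: on DCT
features of typical data it retains a handful of components, on the
7-dimensional morphometrics two or three. `n_components` overrides it for
users who want a fixed dimension (e.g. exactly two for visualization).
Zero-variance columns (the padded DCT tail of an all-identical batch, a
constant morphometric) get their scale forced to 1 with a warning rather
than producing NaNs. Component signs are fixed by making each component's
largest-magnitude loading positive, so refits are comparable.

**FCM.** Standard alternating updates with fuzzifier `m = 2`, tolerance
`1e-5` on the maximum center displacement, 300 iterations maximum, and
seeded initialization from sampled data points. The per-iteration
objective is returned (`objective_trace`) and is non-increasing — a
property the test suite asserts on every run it makes. `clusters_per_class`
defaults to 2: one center per class is a nearest-centroid classifier
(a useful degenerate case the tests exploit), two lets a class express
bimodal waveform structure without inflating the model.

**Classification.** Distances are computed in PC-score space — the
representation the centers were learned in. Exact ties go to the
earliest-stored center (classes are stored in sorted label order, centers
in FCM output order), making predictions order-deterministic.

**Evaluation.** `cross_validate()` stratifies spikes by class into k
near-equal folds under a seed, refits standardization, PCA and FCM on
each training split (no information leaks from held-out spikes into the
scaling), and reports per-class one-vs-rest precision, recall and
accuracy as mean ± SEM over folds. Two switches reproduce laxer or
stricter protocols deliberately: `pca_global = TRUE` fits the PCA once on
all data (a common but leakage-prone shortcut), and `group_by =` keeps
all spikes of one neuron in the same fold (the honest protocol when
spikes within a neuron are strongly correlated; the default spike-level
split matches the classical presentation of this method). Undefined
precision for a never-predicted class is reported as `NA` and excluded
from macro averages with a warning — silently scoring it 0 would bias
comparisons between classifiers.

## The synthetic generator

`make_dataset()` exists so that every stage can be verified in closed
loop: the generator's parameters are the quantities the feature extractor
measures, so recovery can be checked exactly.

Each AP is a half-Gaussian rise and half-Gaussian fall (width ratio
`rise_fall_ratio`) riding on the class's threshold level, followed by an
alpha-function AHP. Two of the parameters are calibrated rather than
plugged in: the Gaussian widths and the AHP depth are adjusted by a short
fixed-point iteration *against the package's own morphometric
measurement* until the realized APD and AHP equal the requested values
(typically < 0.5 % error). This matters because (a) the dV/dt-defined
threshold sits slightly above the nominal baseline, shifting the
half-amplitude level, and (b) the AHP component superposes on the
Gaussian fall; without calibration both realized values would be biased
by several percent for broad spikes.

Class means for APD and AHP follow published in vivo values for mouse
visual cortex: PV 0.70 ms / 12.45 mV, SST 1.18 ms / 7.23 mV, Pyr 1.41 ms
/ 3.06 mV (`preset_specs("paper3")`). Values with no published anchor are
generator conventions, chosen once and flagged in the dataset manifest:
rest −65 mV, amplitude 65 mV, thresholds −40/−44/−42 mV, rise/fall ratios
0.8/0.6/0.5 (PV fastest), per-spike multiplicative jitter with CV 0.05,
Gaussian noise 0.5 mV, 50 Hz line interference of 1 mV. The `allen5`
preset adds VIP and 5HT3a classes with interpolated shape parameters —
synthetic stand-ins, not measurements. Spike times are exponential
inter-spike intervals above a 10 ms refractory floor; every generated
trace returns its ground-truth peak indices, and the manifest regenerates
the dataset bit-identically.

What the generator does *not* emulate — and hence what passing tests do
not show about real recordings: bursting and spike-frequency adaptation
(waveform changes within a train), electrode drift and seal instability,
biophysical waveform families outside half-Gaussian/alpha shapes,
overlapping spikes, and real between-neuron heterogeneity beyond
i.i.d. parameter jitter. Synthetic accuracies are therefore a
verification of the machinery, not a forecast of field performance.

## Numerical choices

* **Notch realization.** The band-stop is designed with `signal::butter`
  but *filtered* as cascaded biquads: at a 5 Hz-wide notch on 20 kHz
  data the poles sit ≈ 0.9995 from the origin and the expanded
  order-6 polynomial loses most of its stop-band depth to rounding
  (measured |H(50 Hz)| ≈ 0.1 instead of ~0). The transmission zeros of a
  band-stop all lie exactly on the unit circle at one angle, so the zero
  sections are rebuilt analytically from the mean root angle and the
  gain renormalized to unity at DC; the measured notch floor is then
  below 1e-4 single-pass. Forward-backward application uses
  odd-reflection padding of `3·fs/bandwidth` samples — long enough for
  the notch's ~¼-second ringing to settle before real data begins.
* **Moving average.** The even default window (8 samples at 20 kHz) is
  split 4 before / 3 after the center; edges use reflection padding. The
  split is arbitrary but fixed, so outputs are reproducible.
* **Plateau peaks** resolve to the earliest sample; **distance ties** to
  the earliest center; **vote ties** to the class with the smaller mean
  winning distance. All three rules exist purely for determinism.
* **FCM coincidence.** A point exactly on a center receives full
  membership there (earliest such center), avoiding 0/0 in the membership
  update.
* **Problem sizes.** The test suite and the acceptance script use the
  default study of 3 classes × 5 neurons × 100 spikes (1500 epochs);
  property checks use 10–200 point fixtures. These sizes give stable
  statistics (SEMs < 1 %) while keeping a full run in seconds.

## A note on the J3 separability index

`j3_index()` computes J3 = trace(S_b + S_w)/trace(S_w) with the
class-size-weighted between-class scatter
S_b = Σᵢ nᵢ (mᵢ − m)ᵀ(mᵢ − m). (The unweighted variant sometimes seen in
print is not computable for unbalanced classes without a convention; the
weighted form is the standard one and reproduces textbook hand examples,
e.g. 1-D classes {0,2} and {10,12} give exactly J3 = 26.)

One property deserves emphasis because it is easy to get wrong when
comparing feature representations: J3 depends only on scatter traces, so
it is invariant under rotation, translation and uniform scaling of the
feature space. The orthonormal DCT of zero-padded epochs *is* an
orthogonal map (padding adds zero columns that contribute nothing to any
scatter), so the unstandardized J3 of the 100 DCT coefficients is
mathematically identical to that of the raw 60-sample epochs — the test
suite asserts this equality. A reported separability gain of DCT over raw
samples therefore necessarily reflects something beyond the rotation:
a non-orthogonal normalization, per-feature standardization, coefficient
selection, or the particular structure of the data it was measured on.
`j3_index(scale = TRUE)` exposes the standardized variant for such
comparisons; on the synthetic default data neither the standardized nor
the literal-α variant ranks DCT above raw epochs, and the package makes
no claim that one representation dominates the other on this index.

## Known limitations

* The classifier is shape-only by design; firing-pattern features (ISI
  statistics, adaptation) would likely help and are deliberately out of
  scope.
* Neuron-level calls use unweighted majority voting; spikes are not
  weighted by confidence.
* The minimum-distance rule is isotropic in PC space; Mahalanobis or
  per-class metrics are not provided.
* Reading native acquisition formats (ABF, NWB, LabVIEW) is out of
  scope: traces enter as plain delimited text with a `fs_hz` header, or
  as pre-cut spike matrices.
* Spike-level cross-validation lets spikes from one neuron appear in both
  training and test folds; use `group_by =` for leave-neurons-out
  estimates when that correlation matters.
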