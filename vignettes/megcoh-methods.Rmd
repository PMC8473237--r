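---
title: "Coherence connectivity and wavelet neuromarkers for MCI detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherence connectivity and wavelet neuromarkers for MCI detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

`megcoh` implements a source-space MEG analysis for discriminating mild
cognitive impairment (MCI) from healthy controls (HC). Starting from ten
ROI-averaged cortical time series per subject (frontal, temporal,
central, parietal, occipital, left/right; 180 s at 200 Hz), it (i)
estimates epoch-wise pairwise magnitude-squared spectral coherence
(MS-COH), summarised over the 0.5–80 Hz broadband, (ii) sums each ROI's
nine pairwise coherences into a per-epoch *degree of connectivity* and
partitions the ROIs into a hyper-connected and a hypo-connected group
according to the sign of the MCI−HC change, (iii) extracts
wavelet-packet neuromarkers from 10-s epochs — the SD of the first
difference of the coefficients of all 14 nodes of a level-3 Daubechies-4
tree — and (iv) classifies observations under two protocols: Monte-Carlo
repeated random splits (MCR) and subject-wise leave-one-out (LOO),
reporting sensitivity, specificity, balanced accuracy and AUC, with
per-dimension t / Kruskal–Wallis screening under Holm–Bonferroni
correction. Because comparable clinical MEG cohorts are not publicly
available, a synthetic-cohort generator with planted class effects is a
first-class module: every downstream stage is tested against structure
known by construction.

## Coherence estimation

The connectivity indicator is
$C_{xy}(f) = |P_{xy}(f)|^2 / (P_{xx}(f)\,P_{yy}(f)) \in [0, 1]$,
with $P_{xy}$ the cross-spectral density. Within a single segment the
estimate is identically 1 regardless of the data, so averaging is
essential; `ms_coherence()` uses Welch's method with 0.5-s Hann
sub-segments at 50% overlap — three averaged segments per 1-s epoch and
a 2 Hz frequency grid at 200 Hz. Sub-segment length and overlap are
configurable through `est_params()`. Two consequences matter for
interpretation:

* With three averaged segments the estimator has a positive bias floor
  of roughly 1/3 for independent signals. Degree-of-connectivity values
  therefore sit near 3 even for uncoupled channels; class *differences*
  are what carry information.
* The broadband summary is the arithmetic mean of the coherence values
  over bins in 0.5–80 Hz (edges inclusive). A sum differs only by a
  constant factor and does not affect any ranking; the mean keeps the
  scalar interpretable in [0, 1].

`pairwise_matrix()` computes each channel's segment FFTs once and forms
all 45 unique pair estimates from them, mirrored into a symmetric matrix
with unit diagonal. Zero-variance inputs yield an explicit
undefined-coherence flag rather than NaN propagation.

## ROI partition

Every ROI participating in at least one pair whose mean coherence
increases in MCI is a hyper-connectivity candidate. With the balance
rule active (the default), the candidate set is trimmed or padded to
exactly five ROIs using the per-ROI degree-of-connectivity delta —
demoting the weakest candidates or promoting the strongest
non-candidates — so that both groups feed the same data volume into
classification. The rule is overridable by an explicit ROI list, because
demotion among near-tied candidates is ultimately a judgment call.
`partition_rois()` records all 45 pair deltas as evidence.

## Wavelet neuromarkers

Each 10-s epoch is (optionally) anti-alias decimated to 200 Hz,
demeaned, and band-pass filtered 0.1–100 Hz with a 4th-order Butterworth
applied forward and backward (zero phase; the effective order doubles).
The upper edge coincides with Nyquist at 200 Hz and is clamped to
0.995 × Nyquist for a realizable filter. The filtered epoch is
decomposed with a Daubechies-4 wavelet packet tree to level 3, keeping
*all* nodes of levels 1–3 (2 + 4 + 8 = 14, deliberately redundant
across levels, enabling multi-resolution views of the same band). Nodes
are labeled in natural (frequency-ascending) order — the Gray-code
reordering of the filter-bank paths — so that the nominal bands tile
0–100 Hz per level and band labels such as "L3_37.5-50Hz" map directly
onto nodes. Boundary handling is half-sample symmetric extension; a
periodic mode exists and is used by the energy-conservation test, where
the orthonormal filter bank conserves energy exactly per level.

The feature of a node is the sample SD (n−1 denominator) of the first
difference of its coefficients. The first difference acts as a crude
high-pass emphasising non-stationary fluctuation of the coefficient
sequence; its SD scales linearly with signal amplitude. A group's five
ROI feature vectors are combined by arithmetic mean into one 14-dim
observation per (subject, epoch) by default; concatenation (70-dim) is
selectable. The mean was chosen as the replication default because the
downstream PCA dimension sweep is naturally interpretable on a 14-dim
space, and because concatenation at 70 dims invites overfitting at
cohort sizes of a few hundred observations.

`pca_reduce()` fits centering and axes on training rows only and
applies them to both sets; the test suite asserts the axes are invariant
to arbitrary modification of test rows.

## Evaluation protocols

* **MCR**: per repeat, a stratified observation-level split holds out
  5% of each class (18 of 360 at reference scale); 20 repeats. Epochs of
  one subject can appear on both sides of the split.
* **LOO** (subject-wise): fold *f* holds out subject *f* of each class;
  no epoch of a held-out subject is ever in training. 20 folds at
  reference scale. A subject-level majority-vote accuracy is reported
  alongside the epoch-level means.

Protocol defaults follow the respective best performers: 3-NN for MCR
and an RBF-kernel SVM (cost 1) for LOO, with LDA, polynomial and linear
kernels available. Features are z-scored with training-set statistics
before distance-based classifiers. Accuracy is epoch-level, matching
the observation counts above; balanced accuracy is by construction the
exact mean of sensitivity and specificity; AUC is the midrank
Mann–Whitney statistic. The MCR−LOO contrast is the package's central
cautionary result: when subjects carry idiosyncratic spectral
fingerprints, pooled-epoch splitting lets the classifier partly
re-identify subjects rather than detect disease, and the honest
subject-wise estimate is systematically lower.

## Statistical screening

Per feature dimension, a pooled-variance Student t-test and a
Kruskal–Wallis test compare the classes; both are two-sided (the
conservative default). Holm–Bonferroni correction is applied within
each test family; the family can span all 14 dimensions or be
restricted to the dimensions whose raw p falls below α, matching the
convention of reporting corrections only for the screened set (the
worked example in the acceptance suite uses m = 6 for exactly this
reason). The Anderson–Darling test (normal family, estimated
parameters) is available for normality screening of coherence sets.

## The synthetic cohort generator

The generator defines the study conditions everything else is tested
under: 20 subjects per class, 10 ROIs, 180 s at 200 Hz (native; a
1000 Hz mode exercises the decimation path), coherence increases planted
on the LF-LT, RT-RC and LP-LO pairs and decreases elsewhere in MCI, and
a class power difference confined to 25–100 Hz.

**Construction.** Within each canonical band (delta 0.5–4, theta 4–8,
alpha 8–12, beta 12–30, gamma 30–80 Hz), each frequency bin's 10-channel
coefficient vector is drawn as $D\,G^{1/2}z$ with $z$ iid complex
Gaussian, $G$ the target coherency-magnitude matrix (unit diagonal,
off-diagonal entries = the pair couplings) and $D$ a diagonal gain. The
cross-spectral matrix of such data is exactly $D G D$, so a pair with
coupling $c$ has planted MS-COH $c^2$, controlled at first order by
$c$, while diagonal gains change spectra without touching coherence.
An earlier design with one shared band-limited source per ROI pair was
abandoned: with nine competing pair sources per channel, MS-COH is
quadratically small (bounded near $(1/9)^2$) and planted decreases sink
below estimator noise.

**Defaults and why.**

| parameter | default | rationale |
|---|---|---|
| `coupling_base` | 0.40 | baseline MS-COH 0.16; with the Welch bias floor this puts degree-of-connectivity means near 3.7, the scale of observed resting-state cohorts |
| `coupling_delta_hyper` | 0.04 | measured pair-coherence increase ≈ +0.015, i.e. degree deltas of order 0.1 — the magnitude range seen across cohort tables |
| `coupling_delta_hypo` | 0.04 | measured pair decrease ≈ −0.012, ≳3 SE of the pair-delta estimate at the 30 s test scale, so the planted sign is recoverable |
| `spectral_effect_size` | 0.3 | +30% power (≈ +14% feature SD) in 25–100 Hz for the six hyper-pair member ROIs; concentrating the feature signal there is what makes the hyper group the better classifier input |
| `subject_sd` | 0.008 | per-pair coupling perturbation; large enough for subject heterogeneity, small enough not to swamp planted deltas |
| `band_gain_sd` | 0.15 | per-subject log band-power gain — the subject fingerprint that produces the MCR-over-LOO optimism gap |
| `noise_sd` | 0.5 | broadband sensor noise at −13 dB per band relative to unit-variance channels |

Couplings perturbed outside [0, 1] are clamped with a logged warning
rather than reject-sampled, so generation remains a pure, reproducible
function of (params, seed); per-subject child seeds derive from the
cohort seed via a fixed linear-congruential step.

**What the generator does and does not emulate.** It reproduces the
pieces the pipeline is sensitive to: controllable pairwise coherence
with class deltas, band-limited spectra with a localized class power
effect, between-subject heterogeneity, and sensor noise. It does not
attempt 1/f spectral shape, non-stationarity, cross-frequency coupling,
volume-conduction leakage, or realistic source geometry. Tests passing
on synthetic cohorts therefore demonstrate that the pipeline recovers
structure of the planted kind at realistic effect sizes — not that any
particular clinical cohort contains such structure.

## Numerical choices and degenerate inputs

* Frequency grid: set by the Welch sub-segment (0.5 s → 2 Hz); band
  edges inclusive.
* Coherence values are clipped into [0, 1] against rounding at the
  1e-9 level; self-coherence is exactly 1 at bins with nonzero power.
* Trailing partial epochs are discarded (`floor(duration/epoch_len)`).
* A single-epoch degree series reports SD 0 (not NA).
* k-NN requires odd k, so binary predictions cannot tie; SVM cost
  defaults to 1 and is echoed in the result config.
* Zero-denominator sensitivities/specificities become NA with a warning
  and are excluded from protocol means.
* `holm_bonferroni()` delegates to `p.adjust(method = "holm")`; the test
  suite holds it against a from-scratch step-down enumeration.

## Problem sizes used by the shipped checks

The test and acceptance runs use the reference scale (20 subjects/class,
180 s) once, to verify the count identities of the full design (45
pairs, 3600 epochs/class/ROI, 324000 coherence evaluations, 360
observations/class), and a reduced scale of 30 s/subject everywhere
results are aggregated over many seeds (partition recovery over 20
seeds, protocol contrasts over 10). At 30 s/subject each class
contributes 600 connectivity epochs and 60 feature observations; these
sizes keep many-seed aggregates affordable while leaving the planted
effects ≳3 SE above estimator noise.

## Known limitations

* Spectral-estimation parameters are not uniquely determined by a 1-s,
  200-sample epoch; other window/overlap choices give numerically
  different (if monotonically related) coherence tables.
* The balance rule's demotion among statistically near-tied candidates
  is seed-dependent in synthetic data; the planted six-ROI candidate
  set, not a specific demotion, is the tested recovery target.
* Holm corrections restricted to the screened set (m = 6) are
  convention-compatible but conditional on the screen; correcting
  across all 14 dimensions is available and more conservative.
* The generator's subject effects are stationary within a recording;
  protocols differing mainly in their handling of non-stationarity are
  outside what it can compare.
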