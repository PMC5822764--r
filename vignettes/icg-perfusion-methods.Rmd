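---
title: "Methods: dynamic ICG fluorescence perfusion analysis"
author: "icgdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic ICG fluorescence perfusion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement

Indocyanine green binds plasma proteins and fluoresces under near-infrared
light, so after an intravenous bolus the fluorescence time course of a skin
pixel traces blood transit through the underlying vascular bed. The
acquisition protocol modeled here records 120 frames of 768 × 512 pixels at
5-s intervals (10 min) of the dorsum of the feet and hands, beginning with
the injection. Each pixel's time–intensity curve rises from a basal level
when the bolus arrives, peaks, and decays slowly as the dye recirculates
and is cleared; over a 10-minute window the curve does not return to
baseline.

## Curve parameterization

All parameters are computed from the *net* curve: raw intensities minus the
estimated basal intensity, clipped at zero.

**Baseline.** The basal intensity is the mean of all samples strictly
before a provisional onset, defined on the raw curve as the first sample
exceeding `min + 0.10 × (max − min)`; if that is the very first sample the
raw minimum is used. This single deterministic pass breaks the circular
dependency between baseline and onset. On smooth noiseless curves the rule
admits a few sub-threshold rising samples into the baseline window and so
overestimates the baseline by a fraction of a percent of the amplitude;
the synthetic generator's calibration compensates for this (below), and the
oracle tests isolate integration accuracy from this estimator by sharing
its baseline.

**Landmarks.** A centered moving average (default window 3 frames, edges
shrunk symmetrically) smooths the net curve *only* for landmark detection:
the peak is the earliest sample attaining the smoothed maximum, and the
onset is the earliest sample at or above `onset_fraction` (default 0.10)
of the smoothed peak. Ties resolve to the earliest sample. Amplitudes and
integrals always come from unsmoothed data, so smoothing never biases the
reported values.

**Parameters.**

- `i_max` (A.U.): maximum of the unsmoothed net curve — blood volume
  surrogate.
- `t_rising` (s): peak time minus onset time.
- `bfi` (A.U./s): `i_max / t_rising`, the rising-slope flow index. The
  identity `bfi × t_rising = i_max` holds to floating precision for every
  valid extraction and is asserted over 10,000 random curves in the tests.
- `auc` (A.U.·s): trapezoidal integral of the net curve over the full
  acquisition. No tail extrapolation is attempted: curves do not return to
  baseline within the window, so AUC (and MTT) are window-limited by
  construction. This is a known, deliberate bias shared by any analysis of
  per-protocol data.
- `mtt` (s): trapezoid-weighted first temporal moment of the net curve,
  `Σ wᵢ tᵢ Nᵢ / Σ wᵢ Nᵢ` — the standard indicator-dilution reading of mean
  transit time. Time is referenced to acquisition start by default
  (`mtt_reference = "acquisition"`), which matches transit-time magnitudes
  of roughly 280–350 s over a 600-s window; an onset-relative reference is
  available by configuration.

**Validity.** A curve is flagged rather than parameterized when it is
constant; when onset and peak coincide (`degenerate-rise`); or when
`i_max` falls below `noise_floor_k` (default 5) times the pre-onset noise
SD (`low-signal`) — this keeps background pixels from contributing
explosive BFI values to parameter maps. When fewer than three pre-onset
samples exist, the noise SD falls back to the SD of successive differences
divided by √2, which is robust to the slow bolus trend. Negative net
values are clipped to zero so noise below baseline cannot create negative
area or mass.

## Regions

The limb image is divided into digits (toes/fingers) and dorsum: digits
approximate the peripheral arterial input, the dorsum the microvascular
bed. The region value is the parameterization of the *mean curve* (the
per-frame spatial mean over region pixels — "one vector per region per
limb"), which matches one value per region per limb in a clinical summary
table; per-pixel dispersion summaries are kept alongside because parameter
maps are also of interest. Mean-curve-then-parameters was chosen over
parameters-then-mean as the canonical reading; both are available (the
dispersion summary is the latter). Region masks are consumed as label
images (0 background, 1 digits, 2 dorsum); no automatic segmentation of
real images is attempted — the generator always emits ground-truth labels,
closing the pipeline.

## Motion QC

Acquisitions in which the limb moved by more than 1 cm during the initial
3 minutes are excluded (strict inequality, windowed to 180 s). Drift is
estimated as the integer-pixel translation of each frame against frame 0
that maximizes the circular FFT cross-correlation of gradient-magnitude
images; gradients suppress the global intensity ramp of the bolus, and a
3 × 3 box blur of the gradient images averages down pixel noise so the
correlation peak is set by scene structure. Magnitudes convert to cm via
the recorded pixel size (0.5 mm/px default ⇒ 1 cm = 20 px, so integer
resolution is ample). Within the pipeline the decision stage estimates
drift for the frames inside the decision window (the only frames the rule
consults); `estimate_displacement()` itself profiles any requested frames,
and `qc_frames = "all"` restores full profiling in the pipeline. The rule
is applied per limb image; motion is excluded, never corrected.

## Stimulation response

Every subject is imaged at rest and after 3 min of brachial-artery cuff
occlusion (released 1 min before the second acquisition). Rest/post pairs
are matched per (subject, limb, side); responses are the absolute
differences |ΔBFI|, |ΔI_max|, |ΔT_rising| of the digit-region parameters
("the fingers"). Hands only are paired by default — the cuff acts on the
brachial artery and no lower-extremity response is expected — feet can be
included by flag. Responses are per hand, not per subject, matching one
point per hand in the pre-versus-post scatter; the scatter table carries
the perpendicular identity-line distance |post − pre|/√2, zero exactly for
a non-responder.

## Group statistics

Classical (equal-variance) one-way ANOVA, then pairwise two-sample t tests
on the pooled ANOVA mean-square-error scale with a Bonferroni multiplier
equal to the number of pairs (3 for three groups), capped at 1 — the
conventional "ANOVA with post hoc Bonferroni". Welch corrections are
deliberately not applied even though group SDs differ strongly; this
mirrors standard clinical-table practice and is noted here rather than
"fixed". Categorical demographics use Pearson chi-square without
continuity correction. Each limb contributes one observation and `n` is
always reported explicitly; the within-subject correlation of two limbs is
not modeled (no mixed models), consistent with the table layout being
reproduced.

## The synthetic generator

No raw clinical stacks are public, so the generator is the package's
test-bed. Its defaults *are* the study conditions; they were chosen once,
as follows, and are not tuned per experiment.

**Curve family.** Baseline `b` until arrival `t0`; half-cosine rise of
amplitude `A` over `Tr` seconds; washout `ρ + (1 − ρ)·exp(−s/τ)` toward a
retained plateau fraction `ρ`. This family was chosen over a gamma-variate
because `A` and `Tr` map one-to-one onto I_max and T_rising, making ground
truth exact rather than fitted, while `ρ` and `τ` reproduce the
slow recirculation tail. AUC and MTT of the net model curve have closed
forms, used as ground truth and verified against a dt = 1 ms brute-force
oracle in the tests.

**Calibration.** For each group × region the amplitude distribution
targets the reference clinical foot I_max mean ± SD directly (truncated at −2/+2.5
SD as plausibility bounds); the rise time targets I_max/BFI; τ is solved
by root-finding so the noiseless net AUC per unit amplitude matches the
reference AUC/I_max. Because the fractional-onset definition detects onset
about 20% into a half-cosine ramp, and 5-s sampling quantizes landmarks,
the *model* rise time is calibrated by a deterministic grid search so that
the *extracted* T_rising averages to the target over the arrival-time
distribution; a parallel factor (≈ +2–3%) compensates the baseline-bias of
extracted I_max. MTT and AUC are emergent, not fitted — with these choices
the emergent foot MTT lands within one reference SD of its target in every
cell, reproducing the key qualitative structure: C > M > D for toe I_max
and AUC, D slowest (largest MTT).

One reference cell is internally inconsistent with *any* bounded
rise-then-decay curve: the D-group dorsum combination of BFI ≈ 10.6
(⇒ T_rising ≈ 274 s), I_max ≈ 2907 and AUC/I_max ≈ 450 s exceeds the
maximum attainable net duration (`Tr/2 + S ≈ 423 s`) in a 600-s window.
The calibration therefore clamps τ at its upper bound there and accepts
the emergent AUC (≈ 1.2 × 10⁶, within one reference SD); amplitude and
rise time take priority, as everywhere.

**Cohorts.** 14 C, 11 D and 16 M subjects, two limbs each, one stack per
subject × side × condition. Amplitude variance is split 80/20 between
subject and limb levels (lognormal effects preserving the cell mean, the
subject effect clipped at z ∈ [−2, 2.2]); rise-time CV is 0.27 between
subjects and 0.13 between limbs, a compromise: the reference BFI SDs would
require rise-time CVs so large that the reference (small) MTT SDs become
unattainable, so I_max and T_rising means take priority and BFI dispersion
is under-reproduced. Arrival times are normal (SD 6 s, truncated to
8–60 s) around group means (25 s; 35 s for D, whose inflow is slow).

**Images.** Desk-scale 64 × 96 px geometry (an ⅛-scale version of the
512 × 768 acquisition; full size is configurable): five digit strips of
uneven width and length above a rectangular dorsum, background at 30% of
tissue baseline so the pre-bolus scene has the persistent edges real
NIR reflectance provides (and registration needs). Within-region
heterogeneity comes from smooth Gaussian random fields (σ = 4 px):
amplitude ±15%, rise time ±4%, baseline ±5%, arrival ±0.8 s — amplitude
varies with local vessel density while timing varies little within a
region's shared supply, which also keeps the region mean curve's peak
sharp. Noise is additive Gaussian with shot-like scaling
σ = `noise_level`·√I, default `noise_level = 1.5` (about 1.5% of peak at
the control toe amplitude — a realistic CCD regime; the source protocol
constrains neither noise level nor spatial texture, so these are stated
defaults, not claims of fidelity). Generated intensities are clipped at
zero, as detector counts are. Everything is bit-reproducible from
(configuration, seed); each manifest row carries its own derived seed so
any stack regenerates on demand without storing 80-stack cohorts.

**Stimulation.** Per-subject post/pre BFI ratios are lognormal: C centered
at 1.6 (responders), D at 1.25 with a wide spread (heterogeneous, some
hands decrease), M at 1.0 with SD 0.05 (non-responders). The ratio is
split between amplitude (`A ∝ r^0.6`) and rise time (`Tr ∝ r^−0.4`) so
I_max and T_rising both respond, as observed. Hand kinetic values have no
reference table and are plausible same-order values with the group
ordering preserved; hand rise times are kept well above the 5-s frame
interval so BFI quantization noise stays small relative to the responses
being measured.

**What passing tests do and do not show.** The generator emulates the
acquisition geometry, timing, group structure and noise regime — not
optical physics (depth-dependent attenuation, scattering), anatomy
(vessel trees, angiosomes), patient-specific artifacts, or non-rigid
motion. Tests passing on this phantom demonstrate that the *pipeline*
recovers what the model encodes at realistic noise; they cannot certify
performance on clinical images.

## Numerical choices and degenerate inputs

- Trapezoid weights handle non-uniform sampling; MTT uses the same
  weights, so quadrature conventions match between AUC and MTT.
- Peak and onset ties resolve to the earliest sample (determinism).
- Constant curves, onset-equals-peak curves, sub-noise-floor curves and
  empty masks are flagged or raise errors rather than yielding numbers;
  invalid map pixels carry NaN, never 0, so map statistics are unbiased.
- TIFF samples live on a [0, 1] grid; stacks and maps are stored
  normalized with the scale recorded in the YAML sidecar. 32-bit storage
  quantizes at ~2 × 10⁻¹⁰ of the scale — negligible against noise but not
  bit-identical, so round-trip tests assert equality at 10⁻⁸.
- The ANOVA F is reported as NA with a `degenerate` flag when every group
  has zero within-variance (the ratio is 0/0 or infinite).
- Problem sizes in the test suite: the replicate study runs 100 cohorts of
  82 stacks at 64 × 96 px; recovery studies use 1000 curves; the identity
  suite 10,000. These sizes make the full suite complete in roughly a
  quarter hour on a single core while keeping Monte Carlo error far below
  the margins being asserted.

## Known limitations

- Window-limited AUC/MTT (no tail extrapolation) biases both low relative
  to an infinite-window ideal; comparisons across groups share the bias.
- The onset definition is sample-resolution; no sub-sample interpolation.
  At 5-s sampling this quantizes T_rising (and hence BFI) by up to one
  frame interval.
- At peak signal-to-noise 20, the unsmoothed-maximum estimator of I_max
  carries a positive noise bias of order one noise SD at the peak; recovery
  to within 5% of truth is then capped near Φ(1) ≈ 84% per draw — an
  estimator property, not an implementation defect. The acceptance test
  records the measured rates.
- Rigid integer-pixel registration only; non-rigid or sub-pixel motion is
  out of scope (the QC rule excludes, it does not correct).
- Two limbs per subject are treated as independent observations in the
  ANOVA, mirroring the summary-table convention being reproduced.
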