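# icgdyn — dynamic ICG fluorescence perfusion analysis

`icgdyn` analyzes time-series near-infrared fluorescence image stacks
recorded after an intravenous indocyanine green (ICG) bolus, the optical
analogue of a contrast bolus-tracking study. Its users are researchers
quantifying peripheral perfusion — for instance comparing limb blood flow
between healthy controls (C), diabetic patients without complications (D),
and diabetic patients with microvascular complications (M) — from stacks of
the dorsum of the feet and hands acquired at 5-s intervals over 10 minutes
(120 frames).

## The kinetic model

Each pixel (or region) carries a time–intensity curve I(t). After
subtracting the basal (pre-bolus) intensity and clipping at zero, the net
curve N(t) yields the vascular tracer parameters:

| parameter | definition | units | reading |
|---|---|---|---|
| I_max | max N(t) | A.U. | blood volume surrogate |
| T_rising | time from curve onset to peak | s | inflow duration |
| BFI | I_max / T_rising | A.U./s | blood flow index (rising slope) |
| AUC | ∫ N(t) dt over the acquisition | A.U.·s | second volume surrogate |
| MTT | ∫ t·N(t) dt / ∫ N(t) dt | s | mean transit time (first temporal moment) |

Onset is the earliest sample reaching 10% of the smoothed net peak; a
3-frame moving average is used *only* to locate onset and peak — all
amplitudes and integrals are computed on unsmoothed data. Around this core
the package provides digit/dorsum region analysis (digits ≈ arterial
input, dorsum ≈ microvascular bed), per-pixel parameter maps, a rigid-drift
motion QC rule (exclude if drift > 1 cm within the initial 3 min),
rest/post-cuff stimulation pairing (|ΔBFI|, |ΔI_max|, |ΔT_rising|), and the
group statistics (one-way ANOVA with Bonferroni post hoc tests,
chi-square). A calibrated synthetic bolus-transit image generator with
exact ground truth stands in for the clinical recordings, which are not
public.

## Worked example

```r
library(icgdyn)

profile <- group_profiles()                  # calibrated group kinetics
cohort  <- generate_cohort(profile, seed = 1)  # 41 subjects x 2 feet, rest
results <- run_pipeline(cohort)              # QC -> kinetics -> statistics
results
#> <icg_results> 82 items: 82 analyzed, 0 excluded, 0 failed
#>   group comparisons (overall p):  bfi.digit=2.1e-17, bfi.dorsum=1.1e-23,
#>   i_max.digit=9.8e-11, i_max.dorsum=1.5e-10, mtt.digit=2.3e-54,
#>   mtt.dorsum=2.6e-37, auc.digit=4.6e-07, auc.dorsum=8.7e-11

st <- results$stats$table
st[st$parameter == "i_max" & st$region == "digit", c("group","n","mean","sd","p_vs_control")]
#>  group  n     mean       sd p_vs_control
#>      C 28 8858.314 2186.226           NA
#>      D 22 3492.274 1171.517 3.904653e-11
#>      M 32 6558.974 3058.419 1.069551e-03
```

The toe I_max ordering C > M > D with D-vs-C highly significant after
Bonferroni adjustment is the expected fingerprint: diabetics without
complications show the lowest blood volume and slowest transit, while the
complications group looks deceptively control-like except in volume — and,
on the hands, fails to respond to cuff stimulation (see
`analysis/05_stimulation_response.R`).

The `analysis/` directory holds the numbered drivers of the full study:
`01_simulate_cohort.R`, `02_parameter_maps.R`, `03_motion_qc.R`,
`04_group_statistics.R`, `05_stimulation_response.R`. Each is a thin
narrative script over the package functions and writes its tables under
`results/`.

## Methods

The model, its assumptions, every tunable default, the generator
calibration, and known limitations are documented in
`vignettes/icg-perfusion-methods.Rmd`.
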