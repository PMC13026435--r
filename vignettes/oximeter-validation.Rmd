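---
title: "Validating pulse oximeters against arterial blood gas under controlled desaturation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating pulse oximeters against arterial blood gas under controlled desaturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxival)
```

## The problem

Pulse oximeters estimate arterial oxygen saturation optically (SpO2),
and their readings drive clinical decisions — most critically around
the hypoxemia threshold of 88% saturation, below which intensive oxygen
therapy is indicated. Validating a device means comparing its readings
against arterial blood gas (ABG) saturation (SaO2) while saturation is
driven through the hypoxemic range under controlled conditions, then
summarizing agreement with the regulatory accuracy metric A\_rms and
related statistics. `oxival` implements that entire analysis: the
protocol model, the metrics, the desaturation-rate stratification, and
a synthetic study generator so the pipeline is fully testable without
access to any study's raw measurements.

## The desaturation protocol

Saturation is manipulated by setting the end-tidal oxygen tension
(PetO2) with a sequential gas delivery system. The expected arterial
saturation at a set tension $P$ (mm Hg) comes from the Severinghaus
(1979) one-line approximation of the oxyhemoglobin dissociation curve:

$$S(P) = 100\left(\frac{23400}{P^3 + 150P} + 1\right)^{-1}$$

`build_protocol()` encodes the standard three-phase step-down design:

* **Phase 1** — monotone desaturation: PetO2 90, 60, 50, 45, 40, 37,
  34, 32 mm Hg (saturation roughly 97% down to 60%);
* **Phase 2** — recovery hold at 250 mm Hg, long enough to be sampled
  as two plateaus;
* **Phase 3** — interrupted desaturation: 90, 60, 50, 60, 50, 45, 40,
  250 mm Hg, reversing direction mid-descent to probe behavior during
  directional changes.

That is 18 steady-state plateaus; with the default two arterial samples
per plateau a complete participant contributes 36 paired measurements.
Each nominal step lasts 3 minutes: the gas system needs about 2 minutes
to reach and stabilize the new target (`inter_plateau_gap = 120` s
within the step), the first sample is drawn at stabilization and the
second a minute later, right before the next transition. Consecutive
cross-plateau samples are therefore about 2 minutes apart, which is
what makes desaturation rates of 2–3%/min per step drop observable. A
30-minute rest separates Phases 2 and 3.

```{r protocol}
protocol <- build_protocol()
protocol
```

Rounded to integer percent, the Severinghaus estimates at the Phase 1
steps are `r paste(round(severinghaus_sao2(c(90, 60, 50, 45, 40, 37, 34, 32))), collapse = ", ")`.
Published step tables built from lookup curves can differ from this
closed form by one to two points at a few steps (37 and 32 mm Hg in
particular); the package's tests therefore require exact agreement only
where the closed form reproduces the printed staircase and a two-point
tolerance elsewhere, and the package always reports the formula value
rather than guessing at an unstated variant.

Skin tone enters validation studies as an equity covariate; the
individual typology angle (ITA, degrees) from a colorimeter is
classified into six standard bands by `classify_ita()` with boundaries
at 55, 41, 28, 10 and −30 degrees (each boundary belongs to the class
whose printed range includes it; only the very-light bound is strict).

## The synthetic study generator

No raw paired SaO2/SpO2 study tables are publicly deposited, so the
package ships a generator whose output has the statistical structure
the analysis assumes. For each participant the *true* saturation trace
relaxes first-order (time constant `response_time_constant`, default
40 s) toward each step's Severinghaus target; ABG samples are the trace
value plus analyzer noise (default SD 0.3%), reported at 0.1%
resolution. A device reading at time $t$ is

$$\mathrm{round}\Big(\underbrace{\tfrac{1}{W}\textstyle\int_{t-W}^{t} S(u)\,du}_{\text{trailing window}} + \underbrace{b_0 + m\max(0, 95 - S(t))}_{\text{saturation-dependent bias}} + \varepsilon\Big)$$

clipped to [0, 100] and displayed as an integer, or `NA` with a
missingness probability that jumps when true saturation is below 70%.
The trailing rectangular window is the simplest mechanism consistent
with how averaging firmware makes readings lag a rapid desaturation: on
a linear ramp of rate $r$ the window mean sits exactly $rW/2$ behind
the instantaneous truth, and the tests check the generator against that
closed-form oracle.

Default device models (chosen once, to emulate the error magnitudes
reported for a clinical-grade transmissive finger oximeter versus a
reflectance wrist wearable under induced hypoxemia):

| parameter | `finger` | `watch` |
|---|---|---|
| bias at full saturation (%) | 0.5 | 0.8 |
| bias slope (%/% below 95) | 0.08 | 0.15 |
| noise SD (%) | 2.0 | 3.0 |
| averaging window (s) | 10 | 15 |
| base missingness | 0.005 | 0.04 |
| low-saturation boost | 0.01 | 0.12 |

The default cohort has nine participants whose ITA values span the
light-to-brown bands. One master seed drives per-participant and
per-device substreams, so a dataset is byte-reproducible and removing a
participant does not perturb the others. What the generator does *not*
emulate: photoplethysmography waveforms, motion and perfusion
artifacts, skin-tone-dependent bias, and real protocol deviations
(the generator produces the full 324 attempts per device; a real study
loses a few to catheter and scheduling problems). Passing tests
therefore demonstrate that the *analysis* is correct and well
calibrated, not that any physical device meets a threshold.

```{r simulate}
ds <- generate_study_dataset(seed = 42)
head(ds)
```

## Accuracy metrics

With signed errors $e = \mathrm{SpO2} - \mathrm{SaO2}$ pooled over all
valid measurements of all participants (the double-sum definition —
*not* a mean of per-participant means):

* **MDE** $= \bar e$ (positive = overestimation),
* **A\_rms** $= \sqrt{\overline{e^2}}$, the regulatory accuracy metric,
* **Missingness** $= 100 - 100\sum_i v_i / N_{\text{attempted}}$,
* band categorization against the manufacturer's ±2% acceptability
  band (boundary inclusive: an error of exactly 2% counts as within).

These satisfy the identity $A_{rms}^2 = \mathrm{MDE}^2 +
\operatorname{Var}(e)$ (population variance), which the tests enforce
to 1e-10. Agreement is also summarized by Bland–Altman bias and 95%
limits of agreement (bias ± 1.96 SD of the differences) and by A\_rms
in 5% reference-saturation bins from 60 to 100 (half-open bins, top bin
closed). Because no analytic distribution for an RMS of bounded,
non-normal errors is satisfactory, A\_rms confidence intervals use a
seeded percentile bootstrap with measurement-level resampling (10,000
replicates by default); bins with fewer than two pairs report the point
estimate without a CI. A reading exhibits *occult hypoxemia* when
SaO2 < 88 while SpO2 > 92 (both strict) — hypoxemia the device hides.

```{r metrics}
validation_metrics(ds, device = "finger", reps = 2000, seed = 1)
```

## Desaturation-rate stratification

Averaging windows should hurt most when saturation is changing fast,
so errors are compared between measurements taken at high versus low
oxygen desaturation rate (ODR). The per-measurement ODR is the decline
in the *reference* SaO2 since the participant's previous sample, per
minute — the reference is the trusted signal and the exclusion rules
are stated in its terms (computing from SpO2 is supported via
`basis = "spo2"`). The 2%/min threshold is the per-minute translation
of the 4%-in-2-minutes desaturation-index criterion used in sleep apnea
screening; the high stratum is inclusive (ODR ≥ 2).

Before stratifying, fully saturated measurements (SpO2 or SaO2
strictly above 99%) and resaturation measurements (reference rose
relative to the predecessor) are excluded, in that order of precedence;
each participant's first sample has no predecessor and is likewise
outside the stratified analysis (all of these remain in the overall
metrics, which never apply these rules). Errors are then mean-aggregated
per participant within each stratum — one MDE per person per stratum —
and the strata are compared with a classical two-sided paired t test
over participants. Degenerate cases follow a documented convention:
all differences zero gives p = 1; identical nonzero differences give
infinite t, p = 0, with a warning. Normality of the participant-level
differences is left to visual inspection via `qq_points()`.

```{r odr}
ann <- stratify_by_odr(apply_exclusions(compute_odr(ds[ds$device == "finger", ])))
table(ann$exclusion_reason)
pairs <- participant_mde(ann)
paired_t_test(pairs)
```

## Reports and regulatory checks

`run_validation()` assembles everything — overall and hypoxemic
(SaO2 < 88, strict) metric blocks, Bland–Altman, the binned profile,
occult-hypoxemia counts, the ODR analysis, and FDA threshold checks —
into a report that is deterministic given the configuration and seed.
Current FDA 510(k) guidance recommends A\_rms below 3% for transmissive
and below 3.5% for reflectance sensors; the 2025 draft standardizes
both to 3% (`guidance = "draft_2025"`). The comparison is strict, so an
A\_rms of exactly 3.0% fails. Displayed numbers are rounded to two
decimals; the JSON form (`report_json()`) keeps full precision.

```{r report, eval = FALSE}
report <- run_validation(list(simulate = TRUE, seed = 42))
report
```

## Numerical choices and limitations

* **Simulation sizes.** The bundled tests run the generator at the
  study's own scale (9 participants × 2 devices × 324 attempts) with
  reduced bootstrap replicate counts where only determinism or
  bracketing is being checked; the type-I-error calibration uses 1000
  replicates of the 9-participant paired design.
* **Boundary conventions.** Band membership is inclusive at ±2; the
  hypoxemia subset, the occult rule and the >99% saturation exclusion
  are strict; the ODR high stratum is inclusive at 2%/min. Each follows
  the wording of the corresponding clinical definition.
* **Ceiling effects.** Integer display clipped to 100 compresses errors
  at near-full saturation, so parameter-recovery checks are performed
  below the ceiling; real analyses inherit the same compression from
  real devices.
* **Known limitations.** Plain Bland–Altman limits ignore
  repeated-measures correlation within participants; Deming or
  Passing–Bablok regression and nonparametric stratum comparisons
  (Wilcoxon) are deliberate non-goals. The generator's first-order lag
  and rectangular window are idealizations; exponential display
  smoothing would be a drop-in alternative but is not implemented.
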