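# oxival

Pulse oximeters estimate arterial oxygen saturation optically (SpO2),
but the readings that matter most clinically — those near and below the
hypoxemia threshold of 88% — are exactly where the devices are least
reliable. Validating a device means driving saturation through the
hypoxemic range under a controlled gas-delivery protocol, pairing each
device reading with a simultaneous arterial blood gas (ABG) reference
value (SaO2), and summarizing agreement with the regulatory metrics.
`oxival` implements that analysis end to end for biostatisticians and
device-validation engineers:

* the **Severinghaus oxygen dissociation model**
  `S(P) = 100 · (23400 / (P³ + 150P) + 1)⁻¹` and the three-phase
  stepwise PetO2 desaturation protocol built on it (18 steady-state
  plateaus, 2 arterial samples each);
* a **synthetic study generator** — first-order physiological lag
  toward each step target, saturation-dependent device bias,
  trailing averaging-window lag, and saturation-dependent missingness —
  so the whole pipeline is testable without any study's raw data;
* the **accuracy metrics**: pooled mean directional error
  (MDE = mean of SpO2 − SaO2), accuracy root-mean-square difference
  (A_rms = √mean (SpO2 − SaO2)², with seeded percentile-bootstrap CIs),
  missingness, and ±2% acceptability-band categorization;
* **Bland–Altman** bias and 95% limits of agreement, **5%-binned A_rms
  profiles** (60–100%), hypoxemia subsetting, and **occult hypoxemia**
  detection (SaO2 < 88 while SpO2 > 92);
* **oxygen desaturation rate (ODR) stratification**: per-measurement
  desaturation rates, saturation/resaturation exclusions,
  ≥ 2%/min stratification, participant-level MDE aggregation, and a
  two-sided paired t test between strata;
* **FDA 510(k) threshold checks** (A_rms < 3% transmissive / < 3.5%
  reflectance; both < 3% under the 2025 draft guidance), assembled by
  `run_validation()` into a deterministic, JSON-serializable report.

## Worked example

```r
library(oxival)

# Severinghaus estimates at the Phase 1 PetO2 steps (mm Hg)
round(severinghaus_sao2(c(90, 60, 50, 45, 40, 37, 34, 32)))
#> [1] 97 91 85 81 75 71 65 62

# a full synthetic study: 9 participants x 2 devices x 36 sample slots
ds <- generate_study_dataset(seed = 42)
head(ds, 4)
#>   participant_id device plateau sample time_s petO2_mmHg sao2_pct spo2_pct phase
#> 1            P01 finger       1      1    120         90     97.1       97     1
#> 2            P01 finger       1      2    180         90     96.5       94     1
#> 3            P01 finger       2      1    300         60     91.0       93     1
#> 4            P01 finger       2      2    360         60     90.4       90     1

validation_metrics(ds, device = "watch", seed = 1)
#> Device: watch
#>   attempted 324, valid 308 (missingness 4.94%)
#>   MDE 2.11%, A_rms 3.93% (95% CI 3.64-4.22%)
#>   band: 154 over / 124 within / 30 under

# accuracy under hypoxemia (reference SaO2 strictly below 88%)
hm <- validation_metrics(hypoxemia_subset(ds[ds$device == "watch", ]), seed = 2)
hm
#> Device: watch
#>   attempted 180, valid 168 (missingness 6.67%)
#>   MDE 3.64%, A_rms 4.69% (95% CI 4.30-5.07%)
#>   band: 123 over / 40 within / 5 under

# does error differ between fast (>= 2%/min) and slow desaturation?
ann <- stratify_by_odr(apply_exclusions(compute_odr(ds[ds$device == "watch", ])))
paired_t_test(participant_mde(ann))
#> Paired t test (two-sided): n=9, mean diff -0.061%, t=-0.146, df=8, p=0.8878

fda_check(hm$arms, "reflectance")$pass   # A_rms 4.69% vs < 3.5% -> FALSE
```

Read top to bottom: the simulated wrist device overestimates saturation
on average (MDE +2.11%), its A_rms of 3.93% worsens to 4.69% in the
hypoxemic range (failing the 3.5% reflectance threshold there), and the
participant-level error difference between fast- and slow-desaturation
measurements is not significant (p = 0.89). `run_validation()` produces
all of the above for every device in one report; `write_measurements()`
/ `read_measurements()` round-trip the measurement table as CSV for
external data.

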