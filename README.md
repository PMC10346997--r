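# hankelppg

Heart-rate estimation from motion-corrupted wrist photoplethysmography (PPG),
for anyone processing wearable PPG + 3-axis accelerometer recordings —
walking and hand-movement scenarios in particular — where motion artifacts
share the heart-rate band and defeat naive spectral estimation.

## Method

The package implements a two-stage pipeline:

**1. Signal-quality gating.** Each analysis window (default 8 s, hop 2 s) is
detrended, z-normalized, and labelled with a binary Signal Quality Token
(SQT). A window qualifies only if

- peak/valley counts satisfy |#valleys − #peaks| ≤ 1 with ≥ 3 beats,
- consecutive inter-beat intervals satisfy |t_{i+1} − t_i| ≤ 0.1 t_i, and
- per-cycle kurtosis, mean and SD fall inside configurable bands.

Unqualified windows carry the previous estimate forward instead of producing
a fresh one.

**2. Hankel/SVD motion-artifact removal.** A window of N samples is embedded
in its L×K Hankel (trajectory) matrix H_ij = a(t_{i+j−1}), L = ⌈N/2⌉,
decomposed as H = UΣVᵀ, and mapped back to per-component time series by
anti-diagonal averaging. Components whose time courses have |Pearson ρ| ≥ 0.5
against the accelerometer (by default against the dominant Hankel/SVD
component series of each axis) are rejected; the survivors are summed back
into a cleaned window. The HR is the spectral peak of the cleaned window
within 0.7–3.5 Hz on a ≤ 0.5 bpm grid, tracked across windows (±10 bpm per
step, initialized at 78 bpm). An adaptive zero-phase notch at the
accelerometer-estimated cadence is available as an alternative artifact
remover for hand movement (`mar_method = "notch"`).

A seeded synthetic generator (`synth_record()`) produces PPG + accelerometer
records with exact ground truth (pulse harmonics, baseline drift,
multi-harmonic cadence artifact coupled into the accelerometer, sensor
noise), so the whole pipeline is testable without external data. Readers for
CSV and IEEE Signal Processing Cup 2015-style MAT records are included.

## Worked example

```r
library(hankelppg)

sim   <- synth_record(synth_params(duration_s = 40, hr_bpm = 72,
                                   motion_freq_hz = 2, artifact_ratio = 2,
                                   seed = 42))
truth <- window_true_hr(sim, 8, 2)
trace <- process_record(sim$record, pipeline_config(mar_method = "hankel"))
trace
#> <hr_trace 'synth-42'>  17 windows, 0 flagged sqt=0
#>   HR: median 72.0 bpm, range 72.0-72.1 bpm
evaluate_hr(trace, truth)
#> <hr_metrics> n = 17 windows (0 with sqt = 0)
#>   ME 0.0486 +/- 0.0227 bpm, MAE 0.0486 bpm
#>   Pearson r = undefined; Bland-Altman LoA [0.00, 0.09] bpm
```

The record carries a walking-like artifact at 2 Hz with twice the pulsatile
RMS; after Hankel/SVD cleaning all 17 windows qualify and the estimates sit
within 0.1 bpm of the 72-bpm truth (Pearson r is undefined here because the
true HR is constant). The same pipeline with `mar_method = "none"` leaves the
cadence peak in place and relies on gating/tracking alone.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/hankelppg.R synth --seed 7 --duration 60 --out rec.csv
Rscript inst/cli/hankelppg.R run   --input rec.csv --format csv --mar hankel --out trace.csv
Rscript inst/cli/hankelppg.R eval  --trace trace.csv --ref rec_truth.csv --report report.json
```

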