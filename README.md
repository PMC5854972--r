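# hfqrs

Automated quantification of the **high-frequency (85–130 Hz) content of
QRS complexes** in multi-lead surface ECG records — a candidate risk
marker for malignant ventricular arrhythmias and sudden cardiac death.
Late, low-amplitude intra-QRS components arising from delayed myocardial
conduction carry energy in this band that visual reading and classical
signal-averaged methods miss; `hfqrs` measures it per beat, per subject
and per cohort.

The package is aimed at cardiac-electrophysiology and biomedical signal
processing groups who want a reproducible, scriptable implementation of
the whole chain, plus a synthetic ECG generator that makes every stage
testable without clinical data.

## What it computes

1. **Beat detection — modified Pan–Tompkins.** On one lead (default II):
   forward difference, squaring, *typification* (clipping at the
   empirical 99.5th percentile P99.5 and dividing by it, so the
   detection signal is scale-free in [0, 1]), a fixed threshold of 0.6
   defining the QRS intervals, and a local-maximum correction that
   places the fiducial `tMaxQRS` at the largest positive V6 voltage.
   Detector quality is scored against reference annotations as
   Se = 100·TP/(TP+FN), PPV = 100·TP/(TP+FP), Er = 100·(FP+FN)/TB.
2. **Window extraction.** 145 ms per beat: 60 ms before to 85 ms after
   `tMaxQRS` (146 samples at 1 kHz).
3. **Morlet continuous wavelet transform.** ψ(t) = π^‑1/4 e^{iω₀t}
   e^{−t²/2} (ω₀ = 6); W(τ,s) = Σ_t x_t s^{−1/2} ψ*((t−τ)dt/s);
   P(τ,s) = |W|²/s, restricted to 85–130 Hz on a 1/125-suboctave scale
   ladder (78 scales, both band edges included).
4. **Metrics.** The per-epoch band power P_τ yields Peak Power, Time to
   Peak Power, Total Power (area), Initial/Final High-Frequency
   Contribution (before / from `tMaxQRS`) and their ratio; the intensity
   function I_t = (1/t)·Σ_{i≤t} P_i (running mean) yields Peak, Time to
   Peak, Final and Total Intensity. Powers are kept in nV²·Hz⁻¹
   internally and reported as 10³ nV²·Hz⁻¹.
5. **Cohort statistics.** Beat→subject means, then per-metric Welch
   t-tests (patient vs control) and chi-square for categorical
   covariates, at α = 0.05.

A 12-lead **synthetic ECG generator** (Gaussian P/QRS/T template,
injectable Gaussian-windowed 85–130 Hz burst with controllable
amplitude/frequency/offset, band-limited noise, known beat times)
drives the test suite and the acceptance script.

## A worked example

```r
library(hfqrs)

res <- runPipeline(pipelineConfig(
  synthesis = list(nControls = 20, nPatients = 10),
  seed = 1, logLevel = "quiet"))
formatCohortTable(res$summary)[c(2, 3, 8, 10), ]
#>                    metric                   control                   patient        p
#> 2      time_to_peak_power         67.04 (+/- 8.642)        79.78 (+/- 0.3315) 2.58e-06
#> 3             total_power 8.526e+14 (+/- 9.119e+13) 6.222e+15 (+/- 4.096e+14) 5.83e-12
#> 8  time_to_peak_intensity         75.06 (+/- 11.93)        94.62 (+/- 0.4895) 5.84e-07
#> 10        total_intensity 7.877e+14 (+/- 1.163e+14)  3.989e+15 (+/- 2.12e+14) 1.68e-14
```

Synthetic "patients" carry a 5× high-frequency burst placed 15 ms later
than controls; the table shows exactly what the method is built to see:
more band power and intensity (total_power, total_intensity, in
10³ nV²·Hz⁻¹ display units), reached later in the QRS
(time_to_peak_*, ms), with Welch p-values from the 20-vs-10 contrast.
Real records enter the same pipeline through a manifest of WFDB or
delimited-text files instead of the `synthesis` block.

A thin CLI wrapping the same functions lives at
`inst/scripts/hfqrs-cli.R` with verbs `analyze`, `simulate`,
`benchmark` and `plot`.

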