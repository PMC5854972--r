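---
title: "Quantifying high-frequency QRS content: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying high-frequency QRS content: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfqrs)
```

## The problem

Notches and late, low-amplitude deflections in the QRS complex reflect
delayed conduction through diseased myocardium and are candidate risk
markers for malignant ventricular arrhythmias and sudden cardiac death.
These features are hard to grade by eye: much of their energy hides in
the 85--130 Hz band, well below the amplitude of the main QRS deflection.
`hfqrs` quantifies that band automatically: it detects beats, aligns a
fixed analysis window on each, computes a Morlet continuous wavelet
transform (CWT) restricted to 85--130 Hz, and collapses the resulting
time--frequency spectrum into a small set of per-beat metrics that are
averaged per subject and contrasted between groups.

## Beat detection and window extraction

Detection works on one lead (default II, configurable). The chain is

1. first-order forward difference, then squaring;
2. *typification*: the squared derivative is clipped at its empirical
   99.5th percentile (P99.5, linear-interpolation definition) and divided
   by it, so the detection signal lies in [0, 1] regardless of the
   record's voltage scale;
3. a fixed threshold of 0.6 marks QRS samples; maximal runs above the
   threshold become candidate intervals. Runs closer than 50 ms merge
   (the squared derivative dips at the R apex, splitting each beat into
   an up-slope and a down-slope run) and merged runs shorter than 5 ms
   are discarded;
4. for each interval, the fiducial `tMaxQRS` is the sample of maximum
   positive voltage in lead V6 -- clinically the lead with the
   best-defined R peak -- searched in the interval dilated by 25 ms,
   ties to the earliest sample. Beats closer than a 200 ms refractory
   period keep the larger V6 peak.

Clipping extremes (rather than deleting them) preserves the time axis;
the percentile normalization is also what makes detection exactly
invariant to global voltage scaling. The moving-window integration stage
of the classical Pan--Tompkins detector is deliberately absent: the
percentile typification plus the fixed threshold takes its place, at the
cost of some noise robustness (see *Limitations*).

The analysis window runs from 60 ms before to 85 ms after `tMaxQRS`,
both endpoints included: 146 samples spanning 145 ms at 1 kHz. Records
at other integer rates are polyphase-resampled to 1 kHz first. Beats
whose window would cross a record boundary are skipped and logged.

## The wavelet transform

The mother wavelet is the Morlet wavelet
$\psi(t) = \pi^{-1/4} e^{i\omega_0 t} e^{-t^2/2}$ with central angular
frequency $\omega_0 = 6$ (configurable). For a series $x_t$ the
transform at scale $s$ and position $\tau$ is the convolution

$$W(\tau, s) = \sum_t x_t \frac{1}{\sqrt{s}}
  \psi^*\!\left(\frac{(t-\tau)\,dt}{s}\right), \qquad
  P(\tau, s) = \frac{1}{s}\,\lvert W(\tau, s)\rvert^2 .$$

No additional $dt$ or reconstruction-factor normalization is applied, so
absolute power is convention-bound; every within-study comparison
(between epochs, beats, subjects or groups) is unaffected. The
implementation evaluates the convolution by FFT after zero-padding to a
power of two large enough that the circular convolution is exact over
the window support (the widest kernel decays below $4\times10^{-18}$ of
its peak inside the padding); the test suite holds the FFT path to
$10^{-8}$ relative agreement with a term-by-term evaluation of the sum.

**Scales.** Adjacent scales differ by $2^{1/125}$ (1/125 suboctave). The
ladder starts at the 130 Hz edge and descends to 85 Hz, whose exact scale
is appended, giving 78 scales whose labeled frequencies all lie inside
the band with both edges included.

**Scale-to-frequency conversion.** With the power normalization above, a
pure tone of frequency $f$ peaks across scales exactly at
$s = \omega_0 / (2\pi f)$. The default conversion therefore labels scale
$s$ with frequency $\omega_0 / (2\pi s)$, so the spectrum of a 100 Hz
cosine peaks at the scale labeled 100 Hz (to within the discretization).
The traditional Morlet Fourier factor
$4\pi/(\omega_0 + \sqrt{2 + \omega_0^2})$ -- derived for conventions that
carry an extra $\sqrt{s}$ in the spectrum -- would mislabel that peak by
about 1.4 %, two to three suboctaves at this resolution; it remains
available via `waveletParams(factorConvention = "fourier")` for
comparison with other software.

**Edges.** A cone-of-influence period is stored per epoch
($\mathrm{ff} \cdot d / \sqrt{2}$ for distance $d$ to the nearer edge)
but power inside it is *not* masked by default: the headline metrics
integrate the whole 145 ms window. Masking is available via
`cwtPower(..., maskCoi = TRUE)`.

**Analysis lead.** The spectrum is computed on the raw voltage of the
alignment lead V6 by default (`lead = "mean"` averages all leads first).
The typified detection signal exists only to find beats; using it for
spectra would destroy the nV$^2$ Hz$^{-1}$ scale. Per-window amplitude
normalization is deliberately not applied: the group contrast is carried
by absolute band power.

## From spectrum to metrics

Summing power over the 78 scales gives the cumulative band-power series
$P_\tau$, one value per epoch of the window. From it:

* **Peak Power** $= \max_\tau P_\tau$; **Time to Peak Power** = epoch of
  the first maximum (ties to the earliest epoch);
* **Total Power** = area under the curve, rectangle rule at 1 ms epochs
  (at this resolution the trapezoid--rectangle difference is < 1 %);
* **Initial / Final High Frequency Contribution** = the part of Total
  Power strictly before / from 60 ms (the `tMaxQRS` epoch) on. The
  60 ms epoch belongs to the *final* part -- the late-potential region
  of interest -- so initial + final = total exactly;
* **Contribution Ratio** = initial / final (NaN-flagged when the final
  part carries no power).

The **intensity function** is the instantaneous average of cumulative
power: the running mean $I_t = \frac{1}{t}\sum_{i \le t} P_i$ over
elapsed epochs. This is the only reading of "1/dt, the time elapsed
until each epoch" consistent with a bounded curve whose value at the
last epoch is the mean of the whole power series. From it: **Peak
Intensity**, **Time to Peak Intensity** (first maximum), **Final
Intensity** ($I_{145\,\mathrm{ms}}$) and **Total Intensity** (area,
rectangle rule). All powers are stored in nV$^2$ Hz$^{-1}$ and divided
by $10^3$ only for display.

Beats aggregate to subjects by the arithmetic mean (median by flag).
Groups are contrasted per metric with Welch's unequal-variance t-test:
the source only says "Student's t-test", but the group SDs of these
metrics differ by an order of magnitude, which makes pooled variance
indefensible; the pooled variant is available via `varEqual = TRUE`.
Categorical covariates use a chi-square test (continuity-corrected for
2x2). Raw p-values are compared against alpha = 0.05 with no
multiple-testing correction, and the run manifest records that choice.

## The synthetic generator

`generateRecord()` builds 12-lead records from an analytic template so
every downstream claim can be tested against known truth:

* each beat is a Gaussian R wave (default FWHM 20 ms -- the width of a
  physiological R peak -- and 1 mV in V6) plus smaller, wider Gaussian
  P and T deflections; per-lead scaling makes V6 the largest positive R
  wave. An inter-beat interval under 300 ms is rejected as
  unphysiological;
* the high-frequency surrogate is a Gaussian-windowed cosine (default
  FWHM 20 ms) at a carrier inside 85--130 Hz, centered at a controllable
  offset from the R peak. Its amplitude, carrier and offset are the
  knobs the cohort tests turn: defaults are 2 % of the R amplitude at
  +5 ms for controls, and the patient template multiplies the amplitude
  by 5 and delays the burst 15 ms more;
* noise is white Gaussian shaped to the magnitude-squared response of a
  4th-order Butterworth low-pass (the net response of a zero-phase
  two-pass filter), default cutoff 100 Hz, scaled to the configured RMS
  (default 20 uV, a typical resting baseline). Surface-ECG noise --
  dominated by muscle artifact and electrode motion -- concentrates
  below ~100 Hz, and the reference arrhythmia database against which
  beat detectors are traditionally scored is itself band-limited to
  100 Hz. Unfiltered white noise at 1 kHz would be physically wrong: it
  fills the octave above 150 Hz that real acquisition chains remove,
  and differentiation-based detection would be dominated by energy no
  sensor delivers. The cutoff is configurable (`noiseBandwidthHz`,
  `Inf` = white); a 50 Hz mains component can be injected to exercise
  the notch-filter path;
* everything is reproducible bit for bit from the config seed; cohorts
  derive per-record seeds deterministically from one master seed.

What the generator does *not* emulate: realistic P/QRS/T morphology
variation, rhythm disturbance (ectopy, atrial fibrillation), baseline
wander, electrode pop, or inter-lead correlated noise. Passing tests
therefore demonstrate the pipeline's arithmetic and its behavior under
controlled band-limited energy and noise -- not clinical performance on
pathological morphologies.

## Numerical choices and degenerate inputs

* Percentile definition: R's default linear-interpolation quantile
  (type 7). An all-zero detection signal (P99.5 = 0) is an error, as is
  a series shorter than 200 samples.
* Peak locations break ties to the earliest epoch; `which.max` gives
  this for free.
* Matching tolerance for detector scoring: +/- 50 ms, one-to-one greedy
  nearest matching; TB is the reference beat count.
* The FFT and direct convolution agree to ~1e-15 relative; the suite
  asserts 1e-8.
* Problem sizes in the test suite were chosen to exercise the study's
  conditions at desk scale: 50 twelve-second records for detector
  scoring, one 120 + 42 cohort for effect-direction recovery, and 200
  cohorts of 20 + 20 for type-I calibration of the full pipeline.

## Known limitations

* With band-limited noise at the top of the tested regime (5 % of the R
  amplitude, i.e. 50 uV RMS), the raw V6 argmax fiducial jitters by
  1--2 ms and a few percent of beats land 3--4 ms from truth. Any
  detector that defines the fiducial as the literal argmax of a noisy
  lead shares this floor; a smoothed or parabolic-interpolated fiducial
  would be more precise but would no longer be the method this package
  implements. The detector's Se/PPV, by contrast, hold comfortably
  (Se about 100 %, PPV about 99 % across the regime).
* The four-step detector (no integration stage) trades noise robustness
  for scale invariance; above roughly 5 % broadband noise its false
  positive rate grows quickly.
* Absolute power values are normalization-convention-bound and should
  only be compared within one convention.
* The Gaussian beat template makes the in-band leakage of the QRS core
  itself symmetric around `tMaxQRS`; real QRS complexes concentrate
  band energy later in the complex, so synthetic contribution ratios
  are not comparable to clinical ones.

## A worked example

```{r example, eval = FALSE}
res <- runPipeline(pipelineConfig(
  synthesis = list(nControls = 20, nPatients = 10),
  seed = 1))
res$summary          # Welch contrasts of all ten metrics
```
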