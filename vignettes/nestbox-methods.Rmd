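---
title: "Methods: contact-free activity, temperature and respiration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact-free activity, temperature and respiration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestboxr)
```

nestboxr is the offline analysis stack for a nest-box imager: a small
instrumented shelter that monitors a free-moving rodent — here a hibernating
model species — with three contact-free sensors. A passive-infrared (PIR)
motion detector in the entrance atrium logs discrete motion events; a
low-resolution (80 x 60 pixel) long-wave thermal camera images the nest
chamber once per second; and a near-infrared video camera records the nesting
animal at 30 frames per second under invisible 890-nm illumination. This
vignette describes the three analysis chains, the synthetic generators used
to test them, and the numerical choices behind both.

## Activity from motion event logs

The PIR sensor emits one timestamp per observed motion event. Events are
treated as point events — the sensor's own dead time is not modelled — and
activity is quantified by counting events in consecutive half-open bins
(default width 60 s; the bin width is an arbitrary-units scale, not a claim
about the sensor). Multiple sensors covering different parts of the cage are
combined by `combine_series()`, each weighted equally by default.

For visualization, `build_actogram()` folds the log into stacked period-long
rows (default period 86,400 s). Only complete periods are kept. Because a
quiescent animal can leave hours without events at the end of a recording,
the fold accepts an explicit recording end (`t_end`); with events alone, the
span would be underestimated.

Agreement between sensing methods is quantified per period:
`compare_to_reference()` bins both signals on a shared grid, forms the
running cumulative sum, normalizes it to end at 1, and computes Pearson's
correlation between the two cumulative curves, then averages across periods.
Periods are intended to start at dark onset so each row spans one
dark-plus-light cycle. Two remarks on this design:

* Correlating *cumulative* curves asks whether two sensors see the same
  daily *shape* of activity. It is deliberately insensitive to absolute
  rates, and it is also structurally generous: any two normalized cumulative
  curves are monotone from 0 to 1 and therefore positively correlated even
  when the underlying signals are unrelated. A near-1 mean r is evidence of
  shared shape; a mid-range r already indicates disagreement.
* When the question is event-level co-occurrence rather than daily shape,
  `method = "counts"` correlates the raw binned counts instead. Two
  independent Poisson streams give counts correlation near zero on this
  scale, which the cumulative scale cannot show. The package's acceptance
  checks use the cumulative scale for the shared-profile comparison and the
  counts scale for the independence control, for exactly this reason.

An all-zero series integrates to all zeros (no division by zero);
`pearson_r()` refuses constant inputs, for which the coefficient is
undefined.

## Surface temperature from thermal frames

Each thermal frame is a 60 x 80 matrix of raw camera counts ("Lepton
units", 14-bit). Two steps map frames to temperature:

1. **Brightest-decile averaging.** The animal rarely fills the field of view
   and may be partly covered by bedding, so the per-frame statistic is the
   mean of the `k = round(fraction * 4800)` largest pixel values, 480 pixels
   at the default `fraction = 0.10`. Rounding of `k` is half-up via R's
   `round()`; ties at the cutoff are broken by value only, so any subset of
   tied values gives the same mean. The statistic is by construction
   invariant to every pixel outside the top-k set — the background-robustness
   property that motivates it. Optionally, dead (0) and saturated (16383)
   pixels can be masked before ranking (`mask_extremes = TRUE`), a guard
   against condensation artifacts on the lens; the default is off.
2. **Linear calibration.** `fit_calibration()` regresses reference
   temperature (response) on raw units (predictor) by ordinary least squares,
   giving `temp_c = slope * raw + intercept` with its r². The direction
   matters: the camera is read out in raw units and converted to Celsius, so
   temperature is the response. Calibration is per camera instance; no
   emissivity or ambient compensation is applied. Calibration pairs come from
   imaging a uniform target (e.g. a thermal-cycler block) at set
   temperatures; for such frames the whole-frame mean (`fraction = 1`) is the
   unbiased readout, while the brightest-decile rule is reserved for
   cluttered in-nest scenes.

One numerical subtlety: under additive pixel noise the mean of the top k
values of a nominally uniform warm region is an order statistic and sits
slightly above the true mean (about 0.65 noise-sd in raw units when the top
480 of ~790 blob pixels are kept). At realistic noise (5 raw units ≈ 0.05 °C)
this bias is ~0.03 °C — negligible against the 12 °C torpor-arousal swing,
but it is why the recovery tolerance in the tests is an absolute 0.1 °C
rather than a pure standard-error bound.

The validation statistic against a contact thermistor is the mean absolute
pairwise deviation, `mean_abs_deviation()`. It accepts either paired series
or precomputed per-condition deviations; the shipped
`extdata/table1_validation.csv` holds the printed per-condition deviations of
the instrument's published validation (seven conditions: two human-hand
proxies and five mice), whose mean is 0.74 °C. The per-condition deviations
in that table were computed over the five replicate images of each condition
before averaging, which is why they differ from the absolute difference of
the tabulated condition means.

## Respiratory rate from video

Breathing moves the animal's flank; a high-contrast spot on the fur (natural
or ink-marked) therefore oscillates at the breathing frequency. The chain is:

1. **Green channel** (`extract_green()`): the channel with the highest
   contrast for this camera.
2. **Binarization** (`binarize()`): pixel ≥ threshold. The threshold is a
   required, user-chosen parameter because feature contrast varies between
   animals; `suggest_threshold()` offers Otsu's value as a starting point,
   as a labelled convenience only.
3. **Centroid tracking** (`track_feature()`): within a user-supplied
   rectangular region of interest, connected components (8-connectivity) are
   labelled and one is selected — by largest area by default, or by
   nearest-to-previous-position, which resists transient distractor shapes.
   Its centroid is the unweighted mean of member pixel coordinates
   (1-based; x = column, y = row). Frames with an empty ROI are marked
   absent.
4. **Moving-window Fourier analysis** (`estimate_frequency()`): for every
   frame with a full centered window (default 26 s), the y-position signal is
   mean-subtracted and discrete-Fourier-transformed; the rate is 60 times the
   frequency of the maximum magnitude within the search band (default
   0.2–5 Hz, bracketing the validated 0.5–4 Hz range). One estimate per
   frame, no zero-padding, so the resolution is one spectral bin,
   `60 / window_s` breaths/min (≈ 2.3 at the default window).
5. **Smoothing** (`smooth_rate()`): a median filter (default 31 points)
   rejects isolated artifact spikes, followed by a centered moving average
   (default 800 points — 26 s at 30 fps). Edge windows shrink instead of
   padding.

Choices the procedure itself does not pin down, and how they were resolved:

* **Window placement** is centered with per-frame stride; an 800-point
  smoothing constant presumes densely sampled output, and centered windows
  keep estimates time-aligned with the motion that produced them. A trailing
  mode exists for causal use.
* **Detrending** defaults to per-window mean subtraction — without DC
  removal the "most prominent peak" would be the zero-frequency bin. An
  optional linear detrend additionally cancels slow drift; the frequency
  estimate is invariant to constant offsets and, with it, to linear drift.
* **Peak definition** is the maximum-magnitude bin; quadratic interpolation
  over the three bins around the peak is available but off by default, so
  the default output is exactly the bin grid.
* **Gap policy**: absent centroids are bridged by linear interpolation for
  gaps up to 0.5 s; windows touching longer gaps are flagged `NA` rather
  than guessed. Rate measurement is only meaningful during relatively
  stationary behaviour, and flagged gaps make those limits visible. A static
  feature (zero in-band power) likewise yields `NA`, not a number.

Low programmed frequencies show a positive bias with short windows: at
30 breaths/min a 13-s window places the true frequency between bins, and
leakage plus noise pushes the argmax upward more often than downward.
Widening the window through 26, 40 and 66 s shrinks this bias monotonically —
a property the test suite checks on synthetic input.

## Synthetic generators

Every analysis stage is tested against generated data with known ground
truth; the generators are first-class, seeded (seed in, identical output
out, caller's RNG state untouched) and emit the same on-disk dialects the
readers parse.

* `gen_motion_events()` draws an inhomogeneous Poisson stream by thinning at
  the profile's peak rate. The default circadian profile is a
  dark-active animal under a 16 h light / 8 h dark "summer" schedule, folded
  so each period starts at dark onset: 6 events/min in the dark phase,
  0.3 events/min in the light.
* `gen_thermal_stack()` renders an elliptical warm body (default ~790 px,
  comfortably above the 480-pixel decile) on a 22 °C background, inverts the
  supplied linear calibration to raw units, adds Gaussian raw-unit noise
  (default sd 5) and quantizes. The default temperature profile is a
  logistic torpor-arousal ramp from 23 to 35 °C.
* `gen_breathing_video()` renders a bright green ellipse whose center
  oscillates along y with instantaneous frequency `bpm_profile(t)/60`
  (default: 60 → 120 breaths/min over 10 minutes, the documented 2-fold
  arousal rise). The edge is soft (logistic profile ~1 px wide) so that the
  binarized blob's centroid tracks the sub-pixel center; amplitude defaults
  to 3 px. Pixel noise and slow drift are optional. A Nyquist check rejects
  frame rates below twice the maximum programmed frequency.

What the generators deliberately do **not** emulate: fur and bedding texture,
illumination flicker, partial occlusion of the thermal view, multiple
animals, and non-respiratory body motion beyond a linear drift term. Passing
recovery tests therefore demonstrates that the algorithms are correct and
stable under noise, quantization and feature selection — not that any given
real recording will contain a trackable feature or an unobstructed thermal
view.

## Problem sizes used in the checks

The recovery checks run on sizes chosen to exercise every code path while
staying light: 64 x 64 px, 30-fps clips of 32–80 s for the frequency sweep
(rates 30–240 breaths/min, noise-free) and the window-bias study (30
breaths/min, pixel noise sd 20); a 48 x 48 px, 10-fps, 14-minute recording
for the torpor-exit fold change; 300–600 thermal frames; and three-day motion
logs. For the fold-change check the 10-minute 60 → 120 ramp is flanked by
two-minute steady torpid and aroused segments so that the smoothed series has
well-defined start and end levels — without plateaus, the start and end of a
centered smoothing window average into the ramp and understate the ratio.
10 fps comfortably satisfies Nyquist for 120 breaths/min (2 Hz) and keeps the
long recording small; the 26-s analysis window then spans 260 samples, the
same 2.3 breaths/min resolution as at 30 fps.

## Known limitations

* Tracking assumes exactly one feature of interest dominates the ROI;
  the nearest-to-previous policy mitigates but does not eliminate distractor
  capture. Heavy locomotion invalidates the stationarity assumption and is
  flagged only indirectly (through gaps and the median filter).
* The thermal chain reports *surface* temperature of the warmest visible
  region; it is a correlate of, not a substitute for, core temperature.
* The frequency estimator reports the dominant in-band peak; when breathing
  amplitude falls below pixel quantization, output is flagged undefined
  rather than degraded gracefully.
* On-disk video is a lossless PNG frame-sequence directory with a small
  JSON sidecar; compressed container formats should be converted to frame
  sequences (e.g. with ffmpeg) before analysis.
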