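---
title: "Modeling pitch contours around brow raises: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling pitch contours around brow raises: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avprosody)
```

## The problem

Speakers raise their eyebrows in tight temporal coordination with pitch
accents. `avprosody` quantifies that coordination from frame-level video
measurements: per frame (30 fps), a speaker's eyebrow height (a normalized
facial-landmark distance), head angles, and pitch (missing on voiceless
frames). The analysis unit is the subtitle segment; within each segment the
frame of maximal standardized eyebrow height — the *eyebrow peak* —
anchors a 121-position window (−60…+60 frames, ±2 s). Two questions drive
the design: over which positions around the peak are eyebrows reliably
elevated (the *raise scope*), and which properties of the pitch contour
just before and after the peak predict how high the brows go?

## Measurement layer

**Eyebrow height** is the distance between the centroid of the ten brow
landmarks and the centroid of four nose landmarks, divided by the
outer-eye-corner distance. The ratio is invariant under translation,
rotation and uniform scaling of the landmark set, so it tracks brow
movement rather than head pose or camera distance. Which four nose points
and which normalizer to use is a free choice; the defaults (0-based
indices: brows 17–26, nose {27, 31, 33, 35}, scale {36, 45}) are
configurable via `geometry_config()`, and per-speaker z-scoring downstream
makes the analysis insensitive to the normalizer.

**Head angles** come from the 3D landmarks: the lateral angle is the roll
of the inter-ocular axis about the camera's depth axis, the sagittal angle
the elevation of the nose-bridge vector out of the frontal plane, both
signed, in degrees, right/up positive.

**Standardization** is per speaker, sample SD (n−1); missing values pass
through untouched and are excluded from the moments. Sample vs population
SD matters only at tiny n; the conventional choice is fixed once.

## Windows and the raise scope

Segments come from SubRip subtitles, converted to half-open frame
intervals `[floor(start·fps), floor(end·fps))` so adjacent subtitles never
share a frame. Peak ties break to the earliest frame (deterministic and
order-independent). Windows truncated by segment boundaries represent the
missing positions as `NA`; raw windows are never imputed — interpolation
happens only inside the fitting step.

The raise scope is estimated positionally: at each window position, a
Mann-Whitney U test compares the heights observed there against the pooled
heights across all positions, Holm-corrected across the 121 positions. The
test is one-sided (*greater*): the scope is the set of positions where
brows are significantly *elevated*. A two-sided version (available via the
`alternative` argument) would also flag far-from-peak positions as
significantly *low* — the pooled mean includes the raise — and is not what
"scope of the raise" means. The test is rank-based, hence invariant under
monotone transformations of the eyebrow scale.

## The sinusoid model

Pre- and post-peak pitch contours are summarized by

$$y(t) = I + A\,\sin(2\pi f t + \varphi\pi)$$

with baseline shift $I$, amplitude $A \ge 0$ (pitch units; z-units by
default), ordinary frequency $f$ (cycles/s) and phase $\varphi \in [0, 2)$
(units of $\pi$ radians; categorized as high-rising $[0, 0.5)$,
high-falling $[0.5, 1)$, low-falling $[1, 1.5)$, low-rising $[1.5, 2)$).
The pre-peak region covers positions $-(w-1)\dots0$ and the post-peak
region $0\dots(w-1)$, both including the peak; the time variable is
seconds with origin at the first fitted frame. Seconds (rather than
frames) make the default window sweeps (10–20 frames) correspond to
sub-cycle to roughly half-cycle pitch excursions at 0.2–1.2 cycles/s,
which is the physiologically sensible regime for single accent-scale pitch
movements; cycles-per-frame parameterizations put plausible contours
beyond Nyquist.

**Estimation.** For fixed $f$ the model is linear in $(I, a, b)$ via
$a\sin + b\cos$, so `fit_sine()` profiles the residual sum of squares over
frequency (variable projection): a dense profile over 0.05–3 cycles/s
seeded with the start frequencies 0.3, 0.6, 1.0, 1.6, 2.4, 1-D refinement
of the best local minima, and a final joint `nls` ("port") polish. The
phase needs no start grid because it is solved exactly at every frequency.
Two guards matter in practice:

* amplitudes are bounded by 5× the data range — at very low frequencies a
  near-linear giant sine arc can "explain" any drifting window — except
  when a candidate fits the data to machine precision (a window sitting
  near a flat sine extremum legitimately has range ≪ A);
* frequencies above ~3 cycles/s are not searched: with 10–20 points and 4
  parameters they only chase interpolation wiggles, and they lie beyond
  the basins of the start grid.

Constant input short-circuits to $A = 0$, $I = \bar y$ with frequency and
phase flagged unidentifiable. `normalize_params()` maps any raw parameter
vector to the unique representative with $A \ge 0$, $f > 0$,
$\varphi \in [0, 2)$ without moving the curve (sign flips absorb into
phase shifts of $\pi$; the wrap is modulo 2).

**Missing pitch.** Voiceless gaps are filled by linear interpolation over
the whole 121-position window (so a gap at a region edge is bridged from
real neighboring values), with nearest-value extension at the window ends.
A region is fitted only if at least 75% of its positions were observed;
otherwise a skip marker records the reason. Competing frequency basins are
compared on the genuinely observed points, since interpolated segments sag
below a curving sine and can otherwise tip the choice.

## Mixed models

Brow-peak magnitude is regressed on the sinusoid parameters with a random
intercept per speaker (`lmerTest::lmer`, REML, Satterthwaite degrees of
freedom). The default predictor set is $\{A, f, \varphi\}$ per region; the
baseline shift $I$ can be included via the `predictors` argument (its
effect is null by design of the standardized scale, and reported tables
conventionally omit it). The combined model joins the pre-region fits at
window 19 (≈630 ms) with the post-region fits at window 17 (≈570 ms) on
segment id and uses $\{A, f, \varphi\}_{pre} \cup \{A, f\}_{post}$ — the
variables significant in the separate models. Window sizes are compared by
AIC of maximum-likelihood refits (REML criteria are kept off the
comparison by convention), ties to the smaller window. Positional summary
curves are penalized cubic-spline smooths (`mgcv::gam`, `k = 30` for the
full sample, `k = 10` for peak-height subsets) with pointwise 95% bands;
the 1.5-SD peak split assigns the boundary to the high set.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with ground truth for recovery testing: five speakers × 150
segments by default, segment lengths ≈ N(68, 32²) frames (≈2.28 s ± 1.08 s
at 30 fps, clamped to 40–200), a Gaussian brow bump (SD 6 frames) of
height $h$ with AR(1) measurement noise (ρ = 0.5, innovation SD 0.1),
windowed sinusoidal pitch excursions whose parameters are drawn uniformly
($A \in [0.2, 3]$, $f \in [0.2, 1.2]$ cycles/s, $\varphi \in [0, 2)$,
$I \in [-1, 1]$), voiceless runs (5% of frames, geometric mean run length
4) and a smooth bounded random walk for pitch outside the coupled windows.
The peak height is linearly coupled to the sine parameters,

$$h = 0.213 + 0.238\,\varphi_{pre} + 0.162\,A_{post} + 0.387\,f_{post}
      + u_{speaker} + \varepsilon,$$

with speaker intercepts $u \sim N(0, 0.3^2)$ and residual
$\varepsilon \sim N(0, 0.6^2)$. The coupling defaults mirror the effect
sizes of the combined-region analysis; the variance components are
declared assumptions (no empirical counterpart is available) chosen so
that t-statistics at n ≈ 750 have realistic magnitudes.

Three generator design choices deserve explanation:

* **Continuity at the peak.** The post-region baseline $I_{post}$ is
  derived so the post sine starts exactly at the pre sine's peak value.
  Blending two discontinuous sines at the peak would make the two
  parameter sets jointly unrecoverable (the shared peak sample would fit
  neither); continuity preserves exact recoverability and is how real
  pitch behaves. Consequently $I_{post}$ is not an independently
  manipulable coupling dimension (its coupling default is 0).
* **Anchoring at the realized peak.** The coupled pitch windows are
  planted around the argmax of the *noisy* eyebrow series, because that is
  where the analysis will center its windows. Anchoring at the noiseless
  bump center would make recovery tests measure window misregistration
  (under the default AR noise the argmax moves off the bump center in most
  segments) rather than the method. With noise off the two anchors
  coincide.
* **Smooth walk.** Out-of-window pitch leaves the sine tangentially with
  momentum (correlated increments), avoiding an artificial derivative
  break at the window edge that linear interpolation would otherwise
  amplify into the fitted region when the edge frames are voiceless.

With bump SD 6, the region where the noiseless bump exceeds its pooled
window average — the generator-truth raise scope — is positions −12…+12,
and the positional test recovers exactly that interval at the default
sample size.

## What passing tests do and do not show

With all noise off the full pipeline recovers the coupling coefficients to
machine precision, and clean (fully voiced) windows recover sinusoid
parameters to 10⁻⁶. At the statistical level (planted peak heights
regressed on planted parameters), single-run estimates at n = 750 lie
within 3 SE of truth and 95% Wald intervals cover at ≈94% over 20
replicates; with only five speakers the intercept's interval undercovers
slightly (≈91% long-run), the familiar small-cluster behavior of Wald
intervals, which Kenward-Roger adjustment does not materially change here.

Running the *full* pipeline on noisy, masked data attenuates the
frequency coupling substantially (to roughly a third of its generative
value): sine parameters estimated from windows with interpolated voiceless
gaps carry heavy-tailed errors — linear interpolation sags below a curving
sine, and for a few windows per run a different frequency basin genuinely
achieves lower least-squares error on the filled series — classic
errors-in-variables. This is a property of the interpolate-then-fit
method itself, not of the implementation; analyses of real corpora with
this method should expect effect sizes for $f$ to be conservative.

The generator emulates coupling structure, voicing gaps and measurement
noise, but not acoustic realities such as pitch declination, microprosody,
speaker-specific pitch ranges, camera cuts, or landmark-tracking failure
modes; passing recovery tests therefore validates the machinery, not the
ecological robustness of conclusions drawn from any particular corpus.

## Numerical choices and degenerate inputs

* Frequency bounds 0.05–5 cycles/s (search band 0.05–3); amplitude bound
  5× data range; `nls` port, tolerance 1e-10, 500 iterations max.
* Constant regions: $A = 0$, $I$ = mean, converged, unidentifiable phase.
* Peak ties → earliest frame; 1.5-SD split boundary → high set; AIC ties →
  smallest window.
* All-missing eyebrow segments are dropped with a message; all-missing
  pitch yields skip-marked fits and `model_unavailable` markers, never an
  error mid-pipeline.
* Subtitle times map to frames by `floor(t·fps + 1e-6)`; the epsilon
  guards against the binary representation of decimal timestamps.
* Test and acceptance problem sizes (n = 750 single runs, 20 replicates
  for coverage, 1000 draws for exact recovery) were chosen to make
  sampling error small relative to the tested tolerances while keeping
  the default suite fast.

## Known limitations

Eyebrow peaks are single frames; multi-peak raises within a segment are
summarized by their maximum only. The sinusoid is a local, single-cycle
approximation — no declination removal, no harmonics. The mixed models use
random intercepts only (no random slopes), matching the reported analysis;
with five speakers, slope variance would be poorly identified anyway.
Phase enters the regressions linearly although it is circular; estimates
near the 0/2 wrap can flip, which contributes to the attenuation discussed
above.
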