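# avprosody

Audiovisual prosody: do eyebrow raises and intonation move together, and
which properties of the pitch contour around a brow raise predict how high
the brows go?

`avprosody` implements a complete analysis pipeline for that question, for
researchers working with frame-level measurements extracted from
conversational video (30 fps): facial-landmark geometry, per-speaker
standardization, subtitle-based segmentation, eyebrow-peak detection,
windowed sinusoidal modeling of pitch contours, and mixed-effects models
linking the sinusoid parameters to brow-peak magnitude. A synthetic-data
generator with known ground truth supports end-to-end validation of every
stage.

## The model

Within each subtitle segment, the frame of maximal standardized eyebrow
height (the *eyebrow peak*) anchors a 121-position analysis window
(positions −60…+60). Pitch contours immediately before and after the peak
are summarized by a four-parameter baseline-shifted sinusoid,

```
y(t) = I + A · sin(2π f t + φπ)
```

with baseline shift `I`, amplitude `A ≥ 0`, ordinary frequency `f`
(cycles/s) and phase `φ ∈ [0, 2)` in units of π radians, fitted by
multi-start profiled least squares to the 19 frames ending at the peak
(pre-peak region, ≈630 ms) and the 17 frames starting at it (post-peak
region, ≈570 ms), with voiceless gaps filled by linear interpolation.
Phases are categorized as high-rising `[0, 0.5)`, high-falling `[0.5, 1)`,
low-falling `[1, 1.5)` and low-rising `[1.5, 2)`. Brow-peak magnitude is
then modeled as

```
peak_height ~ A_pre + f_pre + φ_pre + A_post + f_post + (1 | speaker)
```

by REML with Satterthwaite degrees of freedom.

## Worked example

```r
library(avprosody)

# a synthetic five-speaker corpus with known coupling coefficients
d <- generate_dataset(synthetic_config(seed = 1))
windows <- build_windows(d$frames)

# sinusoid fit for one segment's post-peak contour
fit <- fit_region(windows[[1]], "post", window_size = 17)
print(fit)
#> Baseline-shifted sinusoid fit (17 points)
#>   I = 3.919  A = 2.977  f = 0.58 cycles/s  phi = 1.555 pi rad (low_rising)
#>   r2 = 1.0000

# positional scope of the brow raise
print(raise_scope(windows))
#> Positional scope test (eyebrow, Mann-Whitney vs pooled, holm correction, alpha = 0.05)
#>   significant positions: -12 .. 12 (25 positions)

# mixed model: brow-peak magnitude from pre- and post-peak sine parameters
fp <- fit_table(windows, "pre", 19)
fq <- fit_table(windows, "post", 17)
cm <- combined_model(fp, fq, window_peaks(windows))
print(cm)
#> Mixed model for eyebrow-peak magnitude (combined, n = 587)
#>         term estimate std_error      df t_value p_value
#>  (Intercept)    0.668     0.145  18.007   4.610   0.000
#>        A_pre    0.003     0.026 577.442   0.098   0.922
#>        f_pre    0.058     0.073 577.721   0.800   0.424
#>      phi_pre    0.185     0.042 577.524   4.434   0.000
#>       A_post    0.134     0.027 577.113   4.964   0.000
#>       f_post    0.112     0.069 577.907   1.632   0.103
#> Random intercept (speaker) variance: 0.0467  residual variance: 0.313
```

More compactly, `run_pipeline()` executes every stage and returns a classed
bundle whose `print()` method formats the model tables, the scope interval
and the mean r² per region; `write_bundle()` serializes the seven analysis
artifacts as TSV.

Reading the output: the scope interval −12…+12 is exactly the region where
the generator's noiseless brow bump (SD 6 frames) exceeds its pooled
average — the raise "scope" the positional test is designed to find. In
the mixed model, a later pre-peak phase (`phi_pre`: pitch falling, or
rising from a low point, as the raise begins) and a larger post-peak
amplitude (`A_post`) significantly predict higher brow peaks; the
post-peak frequency effect (`f_post`, generative value 0.387) is
attenuated toward 0.11 because frequency estimates from windows with
interpolated voiceless gaps carry heavy-tailed measurement error (see the
methods vignette).

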