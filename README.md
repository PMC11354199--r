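# ciliafreq

Ciliary beat frequency (CBF) estimation from high-speed video
microscopy of ciliated respiratory epithelium, for researchers and
clinicians evaluating ciliary motility — e.g. in Primary Ciliary
Dyskinesia (PCD) workups — and for methodologists comparing CBF
software against the manual counting reference.

The package implements the three CBF readouts used side by side in
clinical practice, on one common data structure (a `frame_stack`:
time x height x width intensities plus the frame rate):

* **Manual counting (emulated).** On the ROI-mean intensity trace,
  successive maximal-bend landmarks delimit full beats, and

  ```
  CBF (Hz) = (fps / frames elapsed for n beats) x n,   n = 10 by default
  ```

* **Mean-PSD peak.** Per pixel, the one-sided power spectrum
  `|DFT|^2 / N` (mean removed, rectangular window, non-DC bins
  doubled); the CBF is the in-band peak of the pixel-averaged
  spectrum. Grid spacing is `fps / N` — 0.5 Hz at 500 fps over 1000
  frames.

* **Dominant-frequency histogram.** Per pixel, the frequency of the
  in-band spectral maximum; the CBF is the modal bin of the
  histogram of per-pixel dominant frequencies, with per-bin pixel
  percentages.

Around the estimators: readers/writers for multipage TIFF, numbered
PNG sequences, and headerless RAW + text sidecar; pre-processing
(rotation, ROI crop, phase-correlation stabilization with margin
crop, mean-image-subtraction motion extraction); a synthetic
ciliated-patch video generator with exact ground truth; and
normality-routed two-cohort statistics (Kolmogorov–Smirnov
normality, Welch's t vs. one-sample Wilcoxon signed rank,
Pearson vs. Spearman correlation against the manual reference).

## Worked example

Simulate a patch with two ciliated regions beating at 9.5 and
11.5 Hz under sensor noise, then recover the frequencies all three
ways:

```r
library(ciliafreq)

cfg <- sim_config(
  fps = 500, n_frames = 1000, height = 64, width = 64,
  regions = list(
    sim_region("disk", cbf_hz = 9.5,  amplitude = 20, cx = 20, cy = 31, radius = 12),
    sim_region("disk", cbf_hz = 11.5, amplitude = 20, cx = 46, cy = 31, radius = 10)),
  noise_sigma = 4, bit_depth = 8, seed = 42)
sim <- simulate_cilia_stack(cfg)
sim$stack
#> <frame_stack> 1000 frames, 64 x 64 px, 500 fps, 8-bit (synthetic)
#>   duration 2.000 s, intensity range [0, 209]

spec <- pixel_power_spectra(sim$stack, n_frames = 1000, band = c(1, 30))
mean_psd_cbf(spec)
#> <cbf_estimate> 9.5 Hz  [mean_psd_peak]
#>   band 1-30 Hz
```

The mean-PSD peak lands on the stronger (larger) region. The
per-pixel histogram separates the two populations — the variance
floor masks background pixels that carry only noise:

```r
fmap <- dominant_frequency_map(spec, variance_floor = 50)
fmap
#> <cbf_map> 64 x 64 px, 758 defined, band 1-30 Hz (grid 0.5 Hz)

h <- cbf_histogram(fmap)
dplyr::filter(h$distribution, count > 0)
#> # A tibble: 2 x 5
#>   bin_lo bin_hi bin_center_hz count percentage
#>    <dbl>  <dbl>         <dbl> <int>      <dbl>
#> 1   9.25   9.75           9.5   441       58.2
#> 2  11.2   11.8          11.5   317       41.8
```

58% of defined pixels beat at 9.5 Hz and 42% at 11.5 Hz, so the
histogram-mode CBF is 9.5 Hz. The emulated manual count on an ROI
over the left region agrees to frame-rounding precision:

```r
emulate_manual_count(roi_mean_trace(sim$stack, rect_roi(8, 19, 24, 24)))
#> <cbf_estimate> 9.488 Hz  [manual]
```

(9.488 = 500 / 527 x 10: ten 9.5 Hz beats span 526.3 frames, and
landmarks land on whole frames.)

`autoplot()` methods draw the mean spectrum, the frequency heat map,
the histogram, the beat trace, and cohort reports; `tidy()` and
`glance()` return estimates and reports as tibbles. A whole
synthetic cohort runs through `simulate_cohort()` /
`run_pipeline()`, and `build_report()` produces the per-method
medians, IQRs, median differences, routed tests and correlations
for a PCD-vs-control table.

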