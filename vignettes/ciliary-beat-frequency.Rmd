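---
title: "Estimating ciliary beat frequency from high-speed video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ciliary beat frequency from high-speed video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Motile cilia on the respiratory epithelium beat at a characteristic
rate — the ciliary beat frequency (CBF), in Hz — and a depressed CBF
is one of the functional signatures of Primary Ciliary Dyskinesia
(PCD). High-speed video microscopy (hundreds of frames per second)
resolves individual beat cycles, and CBF can then be read out three
ways that are used side by side in clinical evaluation:

1. **Manual counting.** An observer steps through the footage,
   marks the frame where the cilia are closest to their maximal bend,
   counts ten full beats (forward plus recovery stroke), and applies
   `CBF = (fps / frames elapsed) x 10`.
2. **Mean-power-spectrum peak.** Each pixel's intensity time series
   is Fourier-transformed; the per-pixel power spectra are averaged
   over the region of interest (ROI) and the CBF is the frequency of
   the peak of the averaged spectrum.
3. **Dominant-frequency histogram.** Each pixel reports the frequency
   of its own spectral maximum; the per-pixel dominant frequencies
   are histogrammed and the CBF is the modal bin.

`ciliafreq` implements all three routes on one common currency — the
`frame_stack` — together with the pre-processing chain that precedes
them in practice (rotation, ROI cropping, translation stabilization,
margin cropping, motion extraction), cohort-level comparison
statistics, and a synthetic video generator with known ground truth
so that every stage is testable without patient data.

## The pixel model behind the spectral routes

Both software routes treat a beating ciliated patch as a periodic
modulation of pixel intensity. The synthetic generator makes that
model explicit:

$$I(x, y, t) = B(x, y) + \sum_r M_r(x,y)\, A_r
  \sin\!\big(2\pi f_r t / \mathrm{fps} + \phi_r(x, y)\big) + \varepsilon$$

with a static background $B$, region masks $M_r$ beating at $f_r$ Hz
with amplitude $A_r$, an optional linear phase ramp $\phi_r$ of a
stated wavelength and direction (the metachronal wave: neighboring
cilia beat phase-shifted), and i.i.d. Gaussian sensor noise
$\varepsilon$. Frames are then optionally translated by a cumulative
drift (integer pixels, zero fill) and quantized — round half away
from zero, clip to `[0, 2^bit_depth - 1]`, stated so that tests can
be bit-exact.

What the generator deliberately does **not** emulate: cilium shape,
fluid or mucus dynamics, beat-pattern waveform classes, non-rigid
sample deformation, illumination flicker, or camera fixed-pattern
noise. Passing tests on this model therefore demonstrate that the
estimators recover a known periodic signal under noise, drift, and
quantization — not that they are robust to everything real footage
contains.

## Spectral conventions

`pixel_power_spectra()` uses the first `n_frames` frames, removes
each pixel's temporal mean, applies no taper (rectangular window),
and reports the one-sided power spectrum $|X_k|^2 / N$ with the
non-DC, non-Nyquist bins doubled. Two consequences are load-bearing:

* **Parseval:** the one-sided bins of a pixel sum to $N$ times its
  population temporal variance, which the tests verify to float
  tolerance and which supplies the per-pixel variance used by the
  `variance_floor` mask of `dominant_frequency_map()`.
* **Grid exactness:** with no taper, an on-grid sinusoid puts all of
  its power into a single bin, so recovery tests can assert equality
  rather than tolerance.

The frequency grid has spacing `fps / n_frames` — 0.5 Hz for 1000
frames at 500 fps, the configuration the clinical workflows use. A
consequence worth stating plainly: reported spectral CBFs are grid
frequencies, so they are quantized at 0.5 Hz while manual counts are
quantized by frame rounding at roughly $f^2/(\mathrm{fps} \cdot
n_\mathrm{beats})$ — about 0.02 Hz at 10 Hz. An optional quadratic
interpolation of the spectral peak (`interpolate = TRUE`) refines the
estimate off-grid; it is **off** by default so that default output is
exactly reproducible on the grid.

The default analysis band is 1–30 Hz: it excludes DC leakage and
residual drift at the low end and super-physiological frequencies at
the high end, while healthy and PCD beat frequencies (roughly 7–13
Hz) sit well inside. `variance_floor` defaults to 0 — every pixel
with any in-band power is analyzed — because no principled mask rule
exists without a segmentation step; pixels with literally zero
in-band power (noiseless static background) are excluded regardless.

Tie-breaks are lowest-frequency (spectral peak, per-pixel argmax, and
modal histogram bin alike), chosen for determinism.

## Stabilization and motion extraction

Registration is translation-only, estimated by phase correlation of
every frame against one fixed reference frame (default: the first).
Registering against a fixed reference rather than chaining
consecutive pairs avoids accumulating estimation error across the
sequence. After registration the stack is cropped to the maximal
axis-aligned region valid in every frame rather than zero-filled:
fill values would inject spurious broadband power into the spectra.

Phase correlation resolves translations modulo the frame size, so
estimates live in `(-N/2, N/2]` per axis; drifts beyond half a frame
alias. Within that range, integer drifts on synthetic footage are
recovered exactly (the tests assert equality against the generator's
recorded shifts). Ties in the correlation peak break to the lowest
`(dy, dx)` lexicographically. Subpixel refinement is not implemented;
the generator applies integer drift by default precisely so that
recovery is exactly checkable.

Motion extraction is mean-image subtraction: `output[t] = input[t] -
temporal mean image`. It only moves the DC bin — the spectrum above
DC is untouched, which the tests assert — but it matters for
visualization and for any downstream consumer that does not remove
means itself.

The processing order is fixed: rotation, ROI crop, stabilization,
margin crop, motion extraction.

## The emulated manual count

The manual route reduces the ROI to its spatial mean intensity trace,
smooths it with a centered moving average (default width 5 frames),
detects local maxima with a minimum prominence (default 10% of the
smoothed trace's peak-to-peak range), and treats successive maxima as
maximal-bend landmarks: one full beat per interval. The first
landmark is the starting frame; the estimate is the closed-form
formula applied to the frames elapsed over `n_beats` (default 10)
further landmarks.

Two honest caveats. First, the ROI-mean trace is a declared proxy for
what a human counter attends to — a single cilium or cell edge — not
a claim about observer behavior. Second, when a sinusoid's true peak
falls exactly halfway between samples (10 Hz at 500 fps: peaks at
frame 12.5 + 50k), the discrete argmax legitimately lands on either
neighbor, so landmark spacing can jitter by one frame; the formula's
error bound from this rounding is $f^2 / (\mathrm{fps} \cdot
n_\mathrm{beats})$, about 0.017 Hz for 9.2 Hz counted over ten beats
at 500 fps.

## Cohort statistics and routing

`build_report()` reproduces a normality-routed comparison of a PCD
cohort against healthy controls (HC), per method:

* medians and IQRs per group — quartiles by the inclusive
  linear-interpolation rule (R type 7), stated in the report metadata
  because quartile conventions differ across software;
* the actual median difference, HC minus PCD;
* Kolmogorov–Smirnov normality per group, testing against a normal
  with the sample's own mean and SD, no Lilliefors correction;
  `normal` means `p > 0.05`;
* Welch's t test (HC vs PCD) when both groups pass, otherwise a
  one-sample Wilcoxon signed-rank test of the PCD values against the
  HC median — the only reading of a "one-sample" comparison between
  two cohorts that is internally consistent;
* a correlation of the method's per-recording values against the
  manual method per group, Pearson when the method routed parametric
  and Spearman otherwise, computed per recording (no per-subject
  averaging).

The Wilcoxon implementation drops zero differences, mid-ranks ties,
enumerates the exact two-tailed p-value for up to 25 remaining values
(a rank-sum recursion over doubled ranks, which stay integral under
mid-ranks), and switches to the continuity-corrected normal
approximation with the tie-aware variance $\sum r_i^2 / 4$ above
that. The tests pin the exact route to `wilcox.test` on tie-free
data and to closed-form enumerations, and check exact-vs-approximate
agreement within 0.01 at n = 20.

Groups too small for the KS test (n < 5) route nonparametric.

## Reference study conditions

The cohort generator's defaults mirror the acquisition envelope of a
clinical recording session: 500 fps, 1000 analyzed frames, 8-bit
quantization, one ciliated disk per recording, beat amplitude 20
intensity units and sensor noise SD 4 (per-pixel spectral SNR
$A^2/(2\sigma^2) = 12.5$), group CBF distributions parameterized by
exactly the summaries cohort studies report (point mass, median/IQR
normal, uniform). Frame size defaults to desk scale (48 x 48 px for
cohorts, 128 x 128 for single simulations) rather than full sensor
resolution (880 x 637): the estimators are per-pixel, so frame area
changes runtime and pixel counts but not the spectral mathematics,
and the test suite and acceptance script must complete in minutes on
one CPU. These sizes are the package's stated problem sizes
throughout the tests.

`scripts/acceptance.R` runs the end-to-end reference cohort — 50
recordings: 30 PCD across 10 subjects drawn from normal(9.2, 0.5) Hz,
20 HC across 5 subjects from normal(11.1, 0.5) Hz — through all
three methods under identical settings and writes the medians,
median differences, routed p-values and correlations it computes.
One global seed fans out to per-recording child seeds
(`seed + recording index`), so cohorts are reproducible while
recordings stay independent.

## Known limitations

* Translation-only registration; rotational or non-rigid sample
  motion is out of scope, and drifts beyond half a frame alias.
* Spectral output is grid-quantized unless peak interpolation is
  enabled; sub-bin medians cannot be produced at default settings.
* The PNG-sequence dialect writes 8-bit frames only (it reads 8- and
  16-bit); float-valued stacks are stored via the TIFF dialect as
  32-bit float with a plain-text calibration sidecar when values
  leave `[0, 1]`.
* The manual-count emulation is deterministic and therefore has no
  inter-observer variability; it bounds what an idealized counter
  could achieve, not what human counters do.
* No beat-pattern (waveform) analysis, no spatial frequency
  statistics, no particle tracking: the package is about CBF.
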