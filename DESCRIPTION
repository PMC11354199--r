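Package: ciliafreq
Title: Ciliary Beat Frequency Estimation from High-Speed Video Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating ciliary beat frequency (CBF) from
    high-speed video microscopy of ciliated respiratory epithelium.
    Implements three estimation routes used in clinical practice --
    emulated manual beat counting on a region-of-interest intensity
    trace, the peak of the pixel-averaged power spectral density, and
    the mode of the per-pixel dominant-frequency histogram -- together
    with the surrounding pre-processing chain (rotation, ROI cropping,
    translation stabilization by phase correlation, margin cropping,
    and motion extraction by mean-image subtraction), readers and
    writers for TIFF stacks, PNG frame sequences and headerless RAW
    recordings, a synthetic ciliated-patch video generator with known
    ground truth, and normality-routed two-cohort comparison statistics
    (Kolmogorov-Smirnov, Welch's t, one-sample Wilcoxon signed rank,
    Pearson/Spearman correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
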