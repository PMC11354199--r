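#' A single CBF estimate
#'
#' @param value_hz estimated beat frequency, Hz.
#' @param method `"mean_psd_peak"`, `"histogram_mode"` or `"manual"`.
#' @param quality named list of method-specific quality metadata
#'   (peak power, modal bin count, frames elapsed, ...).
#' @param band analysis band `c(f_lo, f_hi)` in Hz containing
#'   `value_hz`.
#' @return An object of class `cbf_estimate`.
#' @export
cbf_estimate <- function(value_hz, method, quality = list(), band = NULL) {
  if (!is.null(band) && (value_hz < band[1] || value_hz > band[2])) {
    abort_cf("estimate lies outside its analysis band.", "bad_estimate")
  }
  structure(list(value_hz = value_hz, method = method,
                 quality = quality, band = band),
            class = "cbf_estimate")
}

#' @export
print.cbf_estimate <- function(x, ...) {
  cat(sprintf("<cbf_estimate> %.4g Hz  [%s]\n", x$value_hz, x$method))
  if (!is.null(x$band)) {
    cat(sprintf("  band %.3g-%.3g Hz\n", x$band[1], x$band[2]))
  }
  invisible(x)
}

#' @rdname cbf_estimate
#' @param x a `cbf_estimate`.
#' @param ... unused.
#' @method tidy cbf_estimate
#' @export
tidy.cbf_estimate <- function(x, ...) {
  tibble(value_hz = x$value_hz, method = x$method,
         band_lo = if (is.null(x$band)) NA_real_ else x$band[1],
         band_hi = if (is.null(x$band)) NA_real_ else x$band[2])
}

#' Per-pixel one-sided power spectra of a frame stack
#'
#' For every pixel, removes the temporal mean of its intensity time
#' series over the first `n_frames` frames (rectangular window, no
#' taper) and computes the one-sided power spectrum
#' `|DFT|^2 / N`, doubling every bin except DC and (for even `N`)
#' Nyquist. The frequency grid has spacing `fps / n_frames` -- 0.5 Hz
#' for 1000 frames at 500 fps. Under this normalization the bins of
#' one pixel sum to `N` times its (population) temporal variance
#' (Parseval).
#'
#' @param stack a [frame_stack()].
#' @param n_frames number of leading frames to analyze; `NULL` uses
#'   all frames.
#' @param band analysis band `c(f_lo, f_hi)` in Hz, inside
#'   `(0, fps/2]`. The full one-sided spectrum is retained; the band
#'   restricts peak picking downstream.
#' @return An object of class `spectrum_stack`: `freqs` (Hz, from 0),
#'   `psd` (bins x pixels matrix, pixels in column-major frame
#'   order), `dim_hw`, `fps`, `n_frames_used`, `band`, and `pixel_var`
#'   (per-pixel temporal variance, for masking).
#' @export
pixel_power_spectra <- function(stack, n_frames = NULL, band = c(1, 30)) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  n <- as.integer(n_frames %||% d[1])
  if (n > d[1]) {
    abort_cf(sprintf("n_frames = %d exceeds the %d available frames.",
                     n, d[1]), "bad_frames")
  }
  if (n < 2L) abort_cf("need at least 2 frames.", "bad_frames")
  nyq <- stack$fps / 2
  if (band[1] <= 0 || band[2] > nyq || band[1] >= band[2]) {
    abort_cf(sprintf("band must lie inside (0, %g].", nyq), "bad_band")
  }
  X <- stack$frames[seq_len(n), , , drop = FALSE]
  dim(X) <- c(n, d[2] * d[3])
  mu <- colMeans(X)
  X <- X - rep(mu, each = n)
  pixel_var <- colMeans(X^2)
  Fx <- stats::mvfft(X)
  k_max <- floor(n / 2)
  psd <- Mod(Fx[seq_len(k_max + 1L), , drop = FALSE])^2 / n
  dbl <- rep(2, k_max + 1L)
  dbl[1L] <- 1
  if (n %% 2L == 0L) dbl[k_max + 1L] <- 1
  psd <- psd * dbl
  freqs <- (0:k_max) * stack$fps / n
  if (!any(freqs >= band[1] & freqs <= band[2] & freqs > 0)) {
    abort_cf("no grid frequencies fall inside the band.", "empty_band")
  }
  structure(
    list(freqs = freqs, psd = psd, dim_hw = c(d[2], d[3]),
         fps = stack$fps, n_frames_used = n, band = band,
         pixel_var = pixel_var),
    class = "spectrum_stack"
  )
}

#' @export
print.spectrum_stack <- function(x, ...) {
  cat(sprintf(
    "<spectrum_stack> %d x %d px, %d bins (0-%.4g Hz, grid %.4g Hz), band %.3g-%.3g Hz\n",
    x$dim_hw[1], x$dim_hw[2], length(x$freqs), max(x$freqs),
    x$fps / x$n_frames_used, x$band[1], x$band[2]))
  invisible(x)
}

band_index <- function(spec) {
  which(spec$freqs >= spec$band[1] & spec$freqs <= spec$band[2] &
          spec$freqs > 0)
}

#' CBF from the peak of the pixel-averaged power spectrum
#'
#' Averages the one-sided power spectra of all analyzed pixels and
#' reports the grid frequency of the maximum inside the analysis band
#' (ties break to the lowest frequency). Optional quadratic
#' interpolation refines the peak off the grid using the two
#' neighboring bins; it is off by default so reported values are grid
#' frequencies.
#'
#' @param spec a [pixel_power_spectra()] result.
#' @param interpolate logical; quadratic peak interpolation.
#' @return a [cbf_estimate()] with method `"mean_psd_peak"`.
#' @export
mean_psd_cbf <- function(spec, interpolate = FALSE) {
  stopifnot(inherits(spec, "spectrum_stack"))
  mp <- rowMeans(spec$psd)
  idx <- band_index(spec)
  if (all(mp[idx] == 0)) {
    abort_cf("no spectral power in band (static input?).", "no_power")
  }
  k <- idx[which.max(mp[idx])]
  f <- spec$freqs[k]
  if (interpolate && k > 1L && k < length(mp)) {
    pl <- mp[k - 1L]; pc <- mp[k]; pr <- mp[k + 1L]
    den <- pl - 2 * pc + pr
    if (den < 0) {
      delta <- 0.5 * (pl - pr) / den
      f <- f + delta * (spec$fps / spec$n_frames_used)
    }
  }
  cbf_estimate(f, "mean_psd_peak",
               quality = list(peak_power = mp[k],
                              mean_psd = mp, freqs = spec$freqs),
               band = spec$band)
}

#' Per-pixel dominant-frequency map
#'
#' For every analyzed pixel, the grid frequency of its in-band power
#' maximum (ties to the lowest frequency). Pixels with temporal
#' variance below `variance_floor`, or with no in-band power at all,
#' are undefined (`NA`) and excluded downstream.
#'
#' @param spec a [pixel_power_spectra()] result.
#' @param variance_floor exclude pixels whose temporal variance falls
#'   below this (intensity squared). Default 0: all pixels with any
#'   in-band power are analyzed.
#' @return An object of class `cbf_map`: `map` (height x width matrix
#'   of Hz, `NA` undefined), `band`, `grid_hz`, `fps`, `n_defined`.
#' @export
dominant_frequency_map <- function(spec, variance_floor = 0) {
  stopifnot(inherits(spec, "spectrum_stack"))
  idx <- band_index(spec)
  sub <- spec$psd[idx, , drop = FALSE]
  total <- colSums(sub)
  # max.col on the transpose, ties.method "first" = lowest frequency
  kk <- max.col(t(sub), ties.method = "first")
  fmap <- spec$freqs[idx][kk]
  undef <- spec$pixel_var < variance_floor | total == 0
  fmap[undef] <- NA_real_
  m <- matrix(fmap, spec$dim_hw[1], spec$dim_hw[2])
  structure(
    list(map = m, band = spec$band,
         grid_hz = spec$fps / spec$n_frames_used, fps = spec$fps,
         n_defined = sum(!undef)),
    class = "cbf_map"
  )
}

#' @export
print.cbf_map <- function(x, ...) {
  cat(sprintf(
    "<cbf_map> %d x %d px, %d defined, band %.3g-%.3g Hz (grid %.4g Hz)\n",
    nrow(x$map), ncol(x$map), x$n_defined, x$band[1], x$band[2],
    x$grid_hz))
  invisible(x)
}

#' Histogram of the per-pixel dominant frequencies
#'
#' Bins the defined pixels of a dominant-frequency map into bins of
#' `bin_width` centered on multiples of `bin_width` (so grid
#' frequencies fall at bin centers), reports per-bin counts and
#' percentages of analyzed pixels, and the histogram-mode CBF: the
#' center of the most occupied bin, ties to the lowest bin.
#'
#' @param fmap a [dominant_frequency_map()] result.
#' @param bin_width histogram bin width in Hz; defaults to the
#'   frequency grid spacing.
#' @return list with `distribution` (a `cbf_distribution` tibble:
#'   `bin_lo, bin_hi, bin_center_hz, count, percentage`) and
#'   `estimate` (a [cbf_estimate()] with method `"histogram_mode"`,
#'   whose quality metadata also carries the pixel-median and
#'   pixel-mean frequency).
#' @export
cbf_histogram <- function(fmap, bin_width = NULL) {
  stopifnot(inherits(fmap, "cbf_map"))
  vals <- fmap$map[!is.na(fmap$map)]
  if (length(vals) == 0L) {
    abort_cf("no defined pixels in the frequency map.", "no_pixels")
  }
  bw <- bin_width %||% fmap$grid_hz
  # bins centered on multiples of bw whose centers stay inside the band
  k_lo <- ceiling(fmap$band[1] / bw - 1e-9)
  k_hi <- floor(fmap$band[2] / bw + 1e-9)
  kv <- floor(vals / bw + 0.5)
  kv <- pmin(pmax(kv, k_lo), k_hi)
  ks <- k_lo:k_hi
  counts <- as.integer(table(factor(kv, levels = ks)))
  centers <- ks * bw
  dist <- new_tibble(
    list(bin_lo = centers - bw / 2, bin_hi = centers + bw / 2,
         bin_center_hz = centers, count = counts,
         percentage = 100 * counts / length(vals)),
    nrow = length(ks), class = "cbf_distribution"
  )
  attr(dist, "bin_width") <- bw
  attr(dist, "band") <- fmap$band
  attr(dist, "n_pixels") <- length(vals)
  mode_i <- which.max(counts)
  est <- cbf_estimate(
    centers[mode_i], "histogram_mode",
    quality = list(bin_count = counts[mode_i],
                   median_hz = stats::median(vals),
                   mean_hz = mean(vals)),
    band = fmap$band
  )
  list(distribution = dist, estimate = est)
}
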