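#' Describe one oscillating ciliated region
#'
#' A region is a pixel mask beating sinusoidally at a fixed frequency,
#' optionally with a metachronal wave: a linear phase ramp across the
#' patch with the given wavelength and direction, emulating the
#' spatially phase-shifted beating of neighboring cilia.
#'
#' @param shape `"rect"`, `"disk"`, or `"mask"`.
#' @param cbf_hz true beat frequency of the region in Hz; must be
#'   below the Nyquist limit `fps / 2` at simulation time.
#' @param amplitude peak intensity modulation (intensity units).
#' @param x0,y0,width,height rectangle geometry (0-based, half-open),
#'   for `shape = "rect"`.
#' @param cx,cy,radius disk geometry (0-based center), for
#'   `shape = "disk"`.
#' @param mask logical height x width matrix, for `shape = "mask"`.
#' @param wavelength_px metachronal wavelength in pixels; `Inf` (the
#'   default) beats in phase everywhere.
#' @param direction_rad direction of the phase ramp, radians.
#' @return An object of class `sim_region`.
#' @export
sim_region <- function(shape = c("rect", "disk", "mask"), cbf_hz, amplitude,
                       x0 = 0, y0 = 0, width = NULL, height = NULL,
                       cx = NULL, cy = NULL, radius = NULL, mask = NULL,
                       wavelength_px = Inf, direction_rad = 0) {
  shape <- match.arg(shape)
  if (!is.numeric(cbf_hz) || length(cbf_hz) != 1L || cbf_hz < 0) {
    abort_cf("`cbf_hz` must be a single number >= 0.", "bad_region")
  }
  check_scalar_number(amplitude, "amplitude")
  structure(
    list(shape = shape, cbf_hz = cbf_hz, amplitude = amplitude,
         x0 = x0, y0 = y0, width = width, height = height,
         cx = cx, cy = cy, radius = radius, mask = mask,
         wavelength_px = wavelength_px, direction_rad = direction_rad),
    class = "sim_region"
  )
}

region_mask <- function(region, height, width) {
  m <- switch(
    region$shape,
    rect = {
      if (region$x0 < 0 || region$y0 < 0 ||
          region$x0 + region$width > width ||
          region$y0 + region$height > height) {
        abort_cf("region mask out of bounds.", "region_oob")
      }
      mm <- matrix(FALSE, height, width)
      mm[(region$y0 + 1):(region$y0 + region$height),
         (region$x0 + 1):(region$x0 + region$width)] <- TRUE
      mm
    },
    disk = {
      xs <- matrix(0:(width - 1), height, width, byrow = TRUE)
      ys <- matrix(0:(height - 1), height, width)
      mm <- (xs - region$cx)^2 + (ys - region$cy)^2 <= region$radius^2
      if (region$cx - region$radius < 0 || region$cy - region$radius < 0 ||
          region$cx + region$radius > width - 1 ||
          region$cy + region$radius > height - 1) {
        abort_cf("region mask out of bounds.", "region_oob")
      }
      mm
    },
    mask = {
      if (!is.matrix(region$mask) || !is.logical(region$mask) ||
          nrow(region$mask) != height || ncol(region$mask) != width) {
        abort_cf("`mask` must be a logical height x width matrix.",
                 "region_oob")
      }
      region$mask
    }
  )
  m
}

region_phase <- function(region, height, width) {
  if (!is.finite(region$wavelength_px)) {
    return(matrix(0, height, width))
  }
  xs <- matrix(0:(width - 1), height, width, byrow = TRUE)
  ys <- matrix(0:(height - 1), height, width)
  proj <- xs * cos(region$direction_rad) + ys * sin(region$direction_rad)
  2 * pi * proj / region$wavelength_px
}

#' Simulation configuration for a synthetic ciliated-patch recording
#'
#' Defines the acquisition envelope (frame rate, frame count, frame
#' size, quantization), the static background, the oscillating
#' regions, sensor noise, and optional global drift. The defaults
#' mirror a 500 fps clinical acquisition analyzed over 1000 frames,
#' at a desk-scale frame size.
#'
#' @param fps frame rate, Hz.
#' @param n_frames number of frames to synthesize (`>= 2`).
#' @param height,width frame size in pixels.
#' @param regions list of [sim_region()] objects.
#' @param background one of: a single number (flat background), a
#'   height x width matrix, or a list
#'   `list(kind = "texture", mean =, amplitude =, smooth_px =)` for a
#'   seeded smooth random texture. Spatial structure in the background
#'   is what translation registration locks onto.
#' @param noise_sigma standard deviation of i.i.d. additive Gaussian
#'   sensor noise (intensity units); `0` disables noise.
#' @param drift `NULL` (none), a `list(kind = "linear", dx_per_frame =,
#'   dy_per_frame =)` spec, or a data frame with columns `dx`, `dy`
#'   giving the cumulative per-frame translation. Shifts are applied as
#'   integer pixel translations with zero fill.
#' @param bit_depth output quantization in bits (round half away from
#'   zero, clip to `[0, 2^bit_depth - 1]`); `NULL` skips quantization
#'   and returns float intensities.
#' @param seed integer seed; identical configurations with identical
#'   seeds produce bit-identical stacks.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fps = 500, n_frames = 1000, height = 128, width = 128,
                       regions = list(),
                       background = list(kind = "texture", mean = 100,
                                         amplitude = 20, smooth_px = 9),
                       noise_sigma = 0, drift = NULL, bit_depth = 8L,
                       seed = 1L) {
  check_scalar_number(fps, "fps", positive = TRUE)
  if (n_frames < 2L) abort_cf("`n_frames` must be >= 2.", "bad_config")
  if (noise_sigma < 0) abort_cf("`noise_sigma` must be >= 0.", "bad_config")
  for (r in regions) {
    if (!inherits(r, "sim_region")) {
      abort_cf("`regions` must be a list of sim_region objects.",
               "bad_config")
    }
    if (r$cbf_hz >= fps / 2) {
      abort_cf(sprintf(
        "region frequency %g Hz violates the Nyquist limit fps/2 = %g Hz.",
        r$cbf_hz, fps / 2), "nyquist")
    }
  }
  structure(
    list(fps = fps, n_frames = as.integer(n_frames),
         height = as.integer(height), width = as.integer(width),
         regions = regions, background = background,
         noise_sigma = noise_sigma, drift = drift,
         bit_depth = if (is.null(bit_depth)) NULL else as.integer(bit_depth),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

build_background <- function(bg, height, width) {
  if (is.matrix(bg)) {
    stopifnot(nrow(bg) == height, ncol(bg) == width)
    return(bg)
  }
  if (is.numeric(bg) && length(bg) == 1L) {
    return(matrix(bg, height, width))
  }
  if (is.list(bg) && identical(bg$kind, "texture")) {
    k <- bg$smooth_px %||% 9L
    noise <- matrix(rnorm(height * width), height, width)
    sm <- box_blur(noise, k)
    sm <- (sm - mean(sm)) / max(sd(as.vector(sm)), .Machine$double.eps)
    return(bg$mean + bg$amplitude * sm)
  }
  abort_cf("unsupported background spec.", "bad_config")
}

# separable box blur with edge replication; enough texture for
# phase-correlation registration to anchor on
box_blur <- function(m, k) {
  if (k <= 1L) return(m)
  if (k %% 2L == 0L) k <- k + 1L
  half <- floor(k / 2)
  pad_idx <- function(n) pmin(pmax(seq(1 - half, n + half), 1L), n)
  mp <- m[pad_idx(nrow(m)), , drop = FALSE]
  cs <- apply(mp, 2L, function(col) {
    s <- cumsum(col)
    (s[(k):length(s)] - c(0, s[seq_len(length(s) - k)])) / k
  })
  mp2 <- cs[, pad_idx(ncol(m)), drop = FALSE]
  t(apply(mp2, 1L, function(row) {
    s <- cumsum(row)
    (s[(k):length(s)] - c(0, s[seq_len(length(s) - k)])) / k
  }))
}

drift_table <- function(drift, n_frames) {
  if (is.null(drift)) {
    return(tibble(frame = seq_len(n_frames), dx = 0L, dy = 0L))
  }
  if (is.data.frame(drift)) {
    stopifnot(nrow(drift) == n_frames,
              all(c("dx", "dy") %in% names(drift)))
    return(tibble(frame = seq_len(n_frames),
                  dx = as.integer(round(drift$dx)),
                  dy = as.integer(round(drift$dy))))
  }
  if (is.list(drift) && identical(drift$kind, "linear")) {
    t0 <- seq_len(n_frames) - 1L
    return(tibble(frame = seq_len(n_frames),
                  dx = as.integer(round(drift$dx_per_frame * t0)),
                  dy = as.integer(round(drift$dy_per_frame * t0))))
  }
  abort_cf("unsupported drift spec.", "bad_config")
}

translate_frame <- function(m, dy, dx, fill = 0) {
  h <- nrow(m)
  w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  if (length(ys) < 1 || length(xs) < 1 || ys[1] > ys[length(ys)] ||
      xs[1] > xs[length(xs)]) {
    return(out)
  }
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Simulate a synthetic ciliated-patch image sequence
#'
#' Pixel model: `I(x, y, t) = B(x, y) + sum_r M_r(x, y) * A_r *
#' sin(2 pi f_r t / fps + phi_r(x, y)) + eps`, with `phi_r` a linear
#' metachronal phase ramp and `eps` i.i.d. Gaussian sensor noise. The
#' frame is then translated by the cumulative drift (integer pixels,
#' zero fill), and quantized. Ground truth (per-pixel frequency map,
#' true shifts, region table) is returned alongside.
#'
#' @param config a [sim_config()].
#' @return A list with elements `stack` (a [frame_stack()]) and
#'   `truth` (class `cilia_truth`: `frequency_map` height x width
#'   matrix, `NA` outside ciliated masks; `shifts` tibble
#'   `frame, dx, dy` of the applied cumulative drift; `regions`
#'   tibble `region, cbf_hz, amplitude, area_px`).
#' @examples
#' cfg <- sim_config(fps = 500, n_frames = 200, height = 32, width = 32,
#'                   regions = list(sim_region("rect", cbf_hz = 10,
#'                                             amplitude = 20, x0 = 8,
#'                                             y0 = 8, width = 16,
#'                                             height = 16)),
#'                   seed = 7)
#' sim <- simulate_cilia_stack(cfg)
#' sim$stack
#' @export
simulate_cilia_stack <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  h <- config$height
  w <- config$width
  nt <- config$n_frames
  shifts <- drift_table(config$drift, nt)

  out <- withr::with_seed(config$seed, {
    bg <- build_background(config$background, h, w)
    # (time, height*width) layout keeps the per-pixel time series in
    # columns, which mvfft consumes directly downstream
    arr <- matrix(rep(as.vector(bg), each = nt), nrow = nt)
    freq_map <- matrix(NA_real_, h, w)
    reg_rows <- list()
    tvec <- (seq_len(nt) - 1) / config$fps
    for (i in seq_along(config$regions)) {
      r <- config$regions[[i]]
      mask <- region_mask(r, h, w)
      phase <- region_phase(r, h, w)
      idx <- which(mask)
      if (length(idx) > 0 && r$amplitude != 0) {
        S <- sin(outer(2 * pi * r$cbf_hz * tvec, phase[idx], FUN = "+"))
        arr[, idx] <- arr[, idx] + r$amplitude * S
      }
      freq_map[mask] <- r$cbf_hz
      reg_rows[[i]] <- tibble(region = i, cbf_hz = r$cbf_hz,
                              amplitude = r$amplitude,
                              area_px = length(idx))
    }
    if (config$noise_sigma > 0) {
      arr <- arr + rnorm(length(arr), 0, config$noise_sigma)
    }
    list(arr = arr, freq_map = freq_map,
         regions = dplyr::bind_rows(reg_rows))
  })

  arr <- out$arr
  if (!is.null(config$bit_depth)) {
    arr <- quantize_intensity(arr, config$bit_depth)
  }
  dim(arr) <- c(nt, h, w)
  if (any(shifts$dx != 0L | shifts$dy != 0L)) {
    for (t in seq_len(nt)) {
      if (shifts$dx[t] != 0L || shifts$dy[t] != 0L) {
        arr[t, , ] <- translate_frame(arr[t, , ], shifts$dy[t], shifts$dx[t])
      }
    }
  }
  stack <- frame_stack(arr, fps = config$fps,
                       bit_depth = config$bit_depth %||% 32L,
                       source_dialect = "synthetic")
  truth <- structure(
    list(frequency_map = out$freq_map, shifts = shifts,
         regions = out$regions),
    class = "cilia_truth"
  )
  list(stack = stack, truth = truth)
}
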