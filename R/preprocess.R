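#' Rotate every frame about the frame center
#'
#' Multiples of 90 degrees are lossless index permutations (90 and 270
#' swap height and width). Any other angle is resampled by bilinear
#' interpolation about the frame center with zero fill outside the
#' source frame. Positive angles rotate counterclockwise.
#'
#' @param stack a [frame_stack()].
#' @param angle rotation in degrees.
#' @return a rotated [frame_stack()].
#' @export
rotate_frames <- function(stack, angle) {
  stopifnot(inherits(stack, "frame_stack"))
  check_scalar_number(angle, "angle")
  a <- angle %% 360
  if (a == 0) return(stack)
  arr <- stack$frames
  d <- dim(arr)
  if (a %% 90 == 0) {
    quarter_turns <- as.integer(a / 90)
    for (q in seq_len(quarter_turns)) {
      d0 <- dim(arr)
      # 90 deg CCW: out[y', x'] = in[x', W + 1 - y'] done as
      # transpose-of-frames followed by a row flip
      arr <- aperm(arr, c(1L, 3L, 2L))[, d0[3]:1, , drop = FALSE]
    }
    out_bd <- stack$bit_depth
  } else {
    theta <- a * pi / 180
    h <- d[2]; w <- d[3]
    cy <- (h - 1) / 2; cx <- (w - 1) / 2
    xs <- matrix(0:(w - 1), h, w, byrow = TRUE) - cx
    ys <- matrix(0:(h - 1), h, w) - cy
    # inverse mapping of a CCW rotation
    sx <- cos(theta) * xs + sin(theta) * ys + cx
    sy <- -sin(theta) * xs + cos(theta) * ys + cy
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    inside <- function(yy, xx) yy >= 0 & yy <= h - 1 & xx >= 0 & xx <= w - 1
    cl <- function(v, n) pmin(pmax(v, 0), n - 1)
    i00 <- cbind(as.vector(cl(y0, h)) + 1, as.vector(cl(x0, w)) + 1)
    i01 <- cbind(as.vector(cl(y0, h)) + 1, as.vector(cl(x0 + 1, w)) + 1)
    i10 <- cbind(as.vector(cl(y0 + 1, h)) + 1, as.vector(cl(x0, w)) + 1)
    i11 <- cbind(as.vector(cl(y0 + 1, h)) + 1,
                 as.vector(cl(x0 + 1, w)) + 1)
    w00 <- (1 - fy) * (1 - fx); w01 <- (1 - fy) * fx
    w10 <- fy * (1 - fx); w11 <- fy * fx
    valid <- inside(sy, sx)
    out <- array(0, dim = d)
    for (t in seq_len(d[1])) {
      f <- arr[t, , ]
      g <- w00 * f[i00] + w01 * f[i01] + w10 * f[i10] + w11 * f[i11]
      g[!valid] <- 0
      out[t, , ] <- g
    }
    arr <- out
    out_bd <- 32L
  }
  frame_stack(arr, fps = stack$fps, bit_depth = out_bd,
              source_dialect = stack$source_dialect)
}

#' Crop a rectangular region of interest out of every frame
#'
#' Half-open pixel convention: columns `x0 <= x < x0 + width`, rows
#' `y0 <= y < y0 + height` (0-based).
#'
#' @param stack a [frame_stack()].
#' @param roi a [rect_roi()], fully inside the frame bounds.
#' @return the cropped [frame_stack()].
#' @export
crop_roi <- function(stack, roi) {
  stopifnot(inherits(stack, "frame_stack"), inherits(roi, "rect_roi"))
  d <- dim(stack$frames)
  if (roi$x0 + roi$width > d[3] || roi$y0 + roi$height > d[2]) {
    abort_cf(sprintf(
      "ROI (x0=%d, y0=%d, %dx%d) extends past the %dx%d frame.",
      roi$x0, roi$y0, roi$width, roi$height, d[3], d[2]), "roi_oob")
  }
  arr <- stack$frames[, (roi$y0 + 1):(roi$y0 + roi$height),
                      (roi$x0 + 1):(roi$x0 + roi$width), drop = FALSE]
  frame_stack(arr, fps = stack$fps, bit_depth = stack$bit_depth,
              source_dialect = stack$source_dialect)
}

# Integer-pixel translation estimate by phase correlation.
# Returns c(dy, dx) such that `moved` equals `ref` translated by
# (dy, dx). Ties in the correlation peak break to the lowest (dy, dx)
# in lexicographic order for determinism.
phase_correlate <- function(ref, moved) {
  Fa <- stats::fft(ref)
  Fb <- stats::fft(moved)
  R <- Fb * Conj(Fa)
  mag <- Mod(R)
  R <- R / pmax(mag, .Machine$double.eps)
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  mx <- max(r)
  cand <- which(r >= mx - 1e-12 * max(1, abs(mx)), arr.ind = TRUE)
  h <- nrow(ref); w <- ncol(ref)
  dy <- cand[, 1] - 1L
  dx <- cand[, 2] - 1L
  dy <- ifelse(dy > h / 2, dy - h, dy)
  dx <- ifelse(dx > w / 2, dx - w, dx)
  ord <- order(dy, dx)
  c(dy = unname(dy[ord[1]]), dx = unname(dx[ord[1]]))
}

#' Stabilize a stack by translation registration
#'
#' Estimates, for every frame, the integer-pixel translation relative
#' to a fixed reference frame by phase correlation, translates each
#' frame back into register, and crops the result to the maximal
#' axis-aligned region valid in all registered frames (the "margin
#' crop"). Registration is translation-only against one reference
#' frame rather than consecutive-pairwise chaining, which avoids drift
#' accumulation in the estimate itself.
#'
#' @param stack a [frame_stack()] with at least 2 frames.
#' @param reference index of the reference frame (default 1).
#' @return list with `stack` (the registered, margin-cropped
#'   [frame_stack()]) and `shifts`: a tibble `frame, dx, dy` recording
#'   the translation applied to register each frame (the negated
#'   estimated displacement; the reference row is `(0, 0)`).
#' @export
stabilize <- function(stack, reference = 1L) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (reference < 1L || reference > d[1]) {
    abort_cf("`reference` must index a frame.", "bad_arg")
  }
  ref <- stack$frames[reference, , ]
  corr <- matrix(0L, d[1], 2L)
  for (t in seq_len(d[1])) {
    if (t == reference) next
    s <- phase_correlate(ref, stack$frames[t, , ])
    corr[t, ] <- c(-s[["dy"]], -s[["dx"]])
  }
  arr <- stack$frames
  for (t in seq_len(d[1])) {
    if (corr[t, 1] != 0L || corr[t, 2] != 0L) {
      arr[t, , ] <- translate_frame(arr[t, , ], corr[t, 1], corr[t, 2])
    }
  }
  ymin <- 1L + max(0L, max(corr[, 1]))
  ymax <- d[2] + min(0L, min(corr[, 1]))
  xmin <- 1L + max(0L, max(corr[, 2]))
  xmax <- d[3] + min(0L, min(corr[, 2]))
  if (ymin > ymax || xmin > xmax) {
    abort_cf("empty overlap after registration (drift too large).",
             "empty_overlap")
  }
  arr <- arr[, ymin:ymax, xmin:xmax, drop = FALSE]
  shifts <- tibble(frame = seq_len(d[1]),
                   dx = as.integer(corr[, 2]),
                   dy = as.integer(corr[, 1]))
  list(
    stack = frame_stack(arr, fps = stack$fps, bit_depth = stack$bit_depth,
                        source_dialect = stack$source_dialect),
    shifts = shifts
  )
}

#' Motion extraction by mean-image subtraction
#'
#' Subtracts the temporal mean image from every frame, removing the
#' static background so only moving structures retain signal. Output
#' intensities are signed floats; the per-pixel temporal mean of the
#' output is zero, and the power spectrum above DC is untouched.
#'
#' @param stack a [frame_stack()] with at least 2 frames.
#' @return a float-valued [frame_stack()].
#' @export
subtract_mean_image <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  arr <- stack$frames
  d <- dim(arr)
  m <- colMeans(arr)                     # (height, width) temporal mean
  arr <- arr - array(rep(as.vector(m), each = d[1]), dim = d)
  frame_stack(arr, fps = stack$fps, bit_depth = 32L,
              source_dialect = stack$source_dialect)
}
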