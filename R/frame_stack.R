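#' Frame stack: an ordered grayscale image sequence
#'
#' The universal currency of the pipeline: a 3-D intensity array with
#' time as the first dimension, plus the acquisition frame rate and the
#' source quantization. All downstream operations (cropping,
#' stabilization, motion extraction, spectral analysis) consume and
#' return frame stacks.
#'
#' @param frames numeric 3-D array, `time x height x width`. At least
#'   two frames; all values finite.
#' @param fps frame rate in Hz (frames per second), `> 0`.
#' @param bit_depth source quantization in bits (8, 16, or 32 for
#'   float-valued stacks such as motion-extracted output).
#' @param source_dialect optional tag recording where the stack came
#'   from: `"tiff"`, `"png_seq"`, `"raw"`, `"synthetic"`, or `NA`.
#'
#' @return An object of class `frame_stack`: a list with elements
#'   `frames`, `fps`, `bit_depth`, `source_dialect`.
#' @examples
#' arr <- array(runif(4 * 8 * 8, 0, 255), dim = c(4, 8, 8))
#' fs <- frame_stack(round(arr), fps = 500)
#' dim(fs)
#' @export
frame_stack <- function(frames, fps, bit_depth = 8L,
                        source_dialect = NA_character_) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort_cf("`frames` must be a 3-D array (time x height x width).",
             "bad_stack")
  }
  d <- dim(frames)
  if (d[1] < 2L) {
    abort_cf("a frame stack needs at least 2 frames.", "bad_stack")
  }
  if (d[2] < 1L || d[3] < 1L) {
    abort_cf("frame height and width must be >= 1.", "bad_stack")
  }
  if (!all(is.finite(frames))) {
    abort_cf("all intensities must be finite.", "bad_stack")
  }
  check_scalar_number(fps, "fps", positive = TRUE)
  storage.mode(frames) <- "double"
  structure(
    list(
      frames = frames,
      fps = fps,
      bit_depth = as.integer(bit_depth),
      source_dialect = source_dialect
    ),
    class = "frame_stack"
  )
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  dim(stack$frames)[1]
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack> %d frames, %d x %d px, %.6g fps, %d-bit%s\n",
    d[1], d[2], d[3], x$fps, x$bit_depth,
    if (is.na(x$source_dialect)) "" else paste0(" (", x$source_dialect, ")")
  ))
  cat(sprintf("  duration %.3f s, intensity range [%.4g, %.4g]\n",
              d[1] / x$fps, min(x$frames), max(x$frames)))
  invisible(x)
}

#' Rectangular region of interest
#'
#' Pixel rectangle in 0-based coordinates with the half-open
#' convention: covered columns are `x0 <= x < x0 + width`, rows
#' `y0 <= y < y0 + height`.
#'
#' @param x0,y0 top-left corner, 0-based pixels.
#' @param width,height extent in pixels, `>= 1`.
#' @return An object of class `rect_roi`.
#' @examples
#' rect_roi(10, 20, 64, 48)
#' @export
rect_roi <- function(x0, y0, width, height) {
  for (v in list(x0 = x0, y0 = y0, width = width, height = height)) {
    if (!is.numeric(v) || length(v) != 1L || v != round(v)) {
      abort_cf("rect_roi fields must be single integers.", "bad_roi")
    }
  }
  if (x0 < 0 || y0 < 0) abort_cf("ROI origin must be >= 0.", "bad_roi")
  if (width < 1 || height < 1) {
    abort_cf("ROI width and height must be >= 1.", "bad_roi")
  }
  structure(
    list(x0 = as.integer(x0), y0 = as.integer(y0),
         width = as.integer(width), height = as.integer(height)),
    class = "rect_roi"
  )
}

#' @export
print.rect_roi <- function(x, ...) {
  cat(sprintf("<rect_roi> x0=%d y0=%d %dx%d px\n",
              x$x0, x$y0, x$width, x$height))
  invisible(x)
}

#' Full-frame ROI of a stack
#' @param stack a [frame_stack()].
#' @return a [rect_roi()] covering every pixel.
#' @export
full_roi <- function(stack) {
  d <- dim(stack$frames)
  rect_roi(0L, 0L, d[3], d[2])
}
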