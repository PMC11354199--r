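#' ROI-mean intensity trace
#'
#' Reduces the visual counting field to a scalar signal: the spatial
#' mean intensity over the ROI, frame by frame. This trace is the
#' substrate for the emulated manual count.
#'
#' @param stack a [frame_stack()].
#' @param roi a [rect_roi()]; defaults to the full frame.
#' @return An object of class `beat_trace` (`values`, `fps`).
#' @export
roi_mean_trace <- function(stack, roi = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  roi <- roi %||% full_roi(stack)
  cropped <- crop_roi(stack, roi)
  arr <- cropped$frames
  d <- dim(arr)
  dim(arr) <- c(d[1], d[2] * d[3])
  beat_trace(rowMeans(arr), stack$fps)
}

#' @rdname roi_mean_trace
#' @param values numeric intensity-per-frame vector (length >= 2).
#' @param fps frame rate, Hz.
#' @export
beat_trace <- function(values, fps) {
  if (length(values) < 2L || !all(is.finite(values))) {
    abort_cf("a beat trace needs >= 2 finite values.", "bad_trace")
  }
  check_scalar_number(fps, "fps", positive = TRUE)
  structure(list(values = as.numeric(values), fps = fps),
            class = "beat_trace")
}

#' @export
print.beat_trace <- function(x, ...) {
  cat(sprintf("<beat_trace> %d frames at %.6g fps (%.3f s)\n",
              length(x$values), x$fps, length(x$values) / x$fps))
  invisible(x)
}

# prominence of a local maximum: height above the higher of the two
# bases, where each base is the minimum between the peak and the
# nearest higher sample on that side (or the end of the trace)
peak_prominence <- function(s, peaks) {
  vapply(peaks, function(p) {
    hp <- s[p]
    left <- s[seq_len(p - 1L)]
    higher_l <- which(left > hp)
    lbase <- if (length(higher_l)) {
      min(left[(max(higher_l) + 1L):(p - 1L)])
    } else if (length(left)) min(left) else hp
    right <- s[(p + 1L):length(s)]
    higher_r <- which(right > hp)
    rbase <- if (length(higher_r)) {
      min(right[seq_len(min(higher_r) - 1L)])
    } else if (length(right)) min(right) else hp
    hp - max(lbase, rbase)
  }, numeric(1))
}

#' Detect maximal-bend landmarks on a beat trace
#'
#' Emulates pausing the footage at the frames where the cilia are
#' fully bent: the trace is smoothed with a centered moving average,
#' and local maxima with at least the requested prominence are taken
#' as successive maximal-bend landmarks. One full ciliary beat
#' (forward plus recovery stroke) is the interval between successive
#' landmarks.
#'
#' @param trace a [beat_trace()] of length >= 3.
#' @param smooth_width moving-average width in frames (forced odd;
#'   default 5).
#' @param min_prominence minimum peak prominence in intensity units;
#'   default 10% of the smoothed trace's peak-to-peak range.
#' @return An object of class `landmark_set`: a tibble
#'   `frame, value` (1-based frame index, smoothed intensity), with
#'   the detection parameters as attributes.
#' @export
detect_beat_landmarks <- function(trace, smooth_width = 5L,
                                  min_prominence = NULL) {
  stopifnot(inherits(trace, "beat_trace"))
  v <- trace$values
  if (length(v) < 3L) abort_cf("trace too short.", "bad_trace")
  w <- as.integer(smooth_width)
  if (w < 1L) w <- 1L
  if (w %% 2L == 0L) w <- w + 1L
  s <- if (w == 1L) v else as.numeric(stats::filter(v, rep(1 / w, w),
                                                    sides = 2))
  ok <- which(!is.na(s))
  if (length(ok) < 3L) abort_cf("trace too short after smoothing.",
                                "bad_trace")
  lo <- ok[1]; hi <- ok[length(ok)]
  interior <- (lo + 1L):(hi - 1L)
  # first index of a plateau counts as its peak
  is_peak <- s[interior] > s[interior - 1L] & s[interior] >= s[interior + 1L]
  peaks <- interior[is_peak]
  prom_floor <- min_prominence %||%
    (0.1 * (max(s, na.rm = TRUE) - min(s, na.rm = TRUE)))
  if (length(peaks)) {
    prom <- peak_prominence(s[lo:hi], peaks - lo + 1L)
    peaks <- peaks[prom >= prom_floor]
  }
  if (length(peaks) < 2L) {
    abort_cf("insufficient landmarks: signal too flat or too short.",
             "insufficient_landmarks")
  }
  out <- new_tibble(list(frame = as.integer(peaks), value = s[peaks]),
                    nrow = length(peaks), class = "landmark_set")
  attr(out, "smooth_width") <- w
  attr(out, "min_prominence") <- prom_floor
  out
}

#' Closed-form manual CBF
#'
#' The manual counting formula: `CBF (Hz) = (fps / frames elapsed for
#' n_beats full ciliary beats) * n_beats`.
#'
#' @param fps frame rate, Hz.
#' @param frames_elapsed frames spanned by `n_beats` full beats
#'   (`>= 1`).
#' @param n_beats number of full beats counted (default 10).
#' @return a [cbf_estimate()] with method `"manual"`.
#' @examples
#' manual_cbf(500, 500, 10)   # 10 Hz
#' manual_cbf(500, 543, 10)   # 9.208 Hz
#' @export
manual_cbf <- function(fps, frames_elapsed, n_beats = 10L) {
  check_scalar_number(fps, "fps", positive = TRUE)
  if (frames_elapsed < 1 || frames_elapsed != round(frames_elapsed)) {
    abort_cf("`frames_elapsed` must be a positive integer.", "bad_arg")
  }
  if (n_beats < 1) abort_cf("`n_beats` must be >= 1.", "bad_arg")
  cbf_estimate(fps / frames_elapsed * n_beats, "manual",
               quality = list(frames_elapsed = as.integer(frames_elapsed),
                              n_beats = as.integer(n_beats)),
               band = c(0, fps / 2))
}

#' Emulate the manual counting protocol on a trace
#'
#' Detects maximal-bend landmarks, marks the first as the starting
#' frame, counts the frames elapsed until `n_beats` further landmarks
#' have passed, and applies the manual CBF formula.
#'
#' @param trace a [beat_trace()].
#' @param n_beats number of full beats to count (default 10).
#' @param smooth_width,min_prominence landmark detector parameters,
#'   see [detect_beat_landmarks()].
#' @return a [cbf_estimate()] with method `"manual"`; its quality
#'   metadata carries the landmark table.
#' @export
emulate_manual_count <- function(trace, n_beats = 10L, smooth_width = 5L,
                                 min_prominence = NULL) {
  lm <- detect_beat_landmarks(trace, smooth_width, min_prominence)
  if (nrow(lm) < n_beats + 1L) {
    abort_cf(sprintf(
      "insufficient landmarks: %d detected, %d needed for %d beats.",
      nrow(lm), n_beats + 1L, n_beats), "insufficient_landmarks")
  }
  frames_elapsed <- lm$frame[n_beats + 1L] - lm$frame[1L]
  est <- manual_cbf(trace$fps, frames_elapsed, n_beats)
  est$quality$landmarks <- lm
  est
}
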