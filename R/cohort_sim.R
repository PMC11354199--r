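#' Distribution specification for a cohort's true CBF values
#'
#' Cohort generators are parameterized by exactly the summaries
#' clinical studies report: a point mass, a normal with either an
#' explicit SD or an IQR-derived SD (`sd = IQR / (2 * qnorm(0.75))`),
#' or a uniform range.
#'
#' @param kind `"point"`, `"normal"` or `"uniform"`.
#' @param value point-mass value, Hz.
#' @param mean,sd normal parameters, Hz. `median`/`iqr` may be given
#'   instead of `mean`/`sd`.
#' @param median,iqr alternative normal parameterization.
#' @param min,max uniform bounds, Hz.
#' @return An object of class `cbf_dist`.
#' @export
cbf_dist <- function(kind = c("point", "normal", "uniform"),
                     value = NULL, mean = NULL, sd = NULL,
                     median = NULL, iqr = NULL, min = NULL, max = NULL) {
  kind <- match.arg(kind)
  spec <- switch(
    kind,
    point = {
      if (is.null(value)) abort_cf("point spec needs `value`.", "bad_dist")
      list(kind = kind, value = value)
    },
    normal = {
      if (is.null(mean)) mean <- median
      if (is.null(sd) && !is.null(iqr)) sd <- iqr / (2 * stats::qnorm(0.75))
      if (is.null(mean) || is.null(sd) || sd < 0) {
        abort_cf("normal spec needs `mean`/`median` and `sd`/`iqr` >= 0.",
                 "bad_dist")
      }
      list(kind = kind, mean = mean, sd = sd)
    },
    uniform = {
      if (is.null(min) || is.null(max) || min >= max) {
        abort_cf("uniform spec needs `min` < `max`.", "bad_dist")
      }
      list(kind = kind, min = min, max = max)
    }
  )
  structure(spec, class = "cbf_dist")
}

draw_cbf <- function(dist, n, fps) {
  lo <- .Machine$double.eps
  hi <- fps / 2
  support_ok <- switch(
    dist$kind,
    point = dist$value > 0 && dist$value < hi,
    normal = dist$mean > 0 && dist$mean < hi,
    uniform = dist$min > 0 && dist$max < hi
  )
  if (!support_ok) {
    abort_cf("CBF distribution support must lie within (0, fps/2).",
             "bad_dist")
  }
  draws <- switch(
    dist$kind,
    point = rep(dist$value, n),
    normal = rnorm(n, dist$mean, dist$sd),
    uniform = runif(n, dist$min, dist$max)
  )
  # truncate the (rare) normal tail outside the physical support
  bad <- which(draws <= lo | draws >= hi)
  guard <- 0L
  while (length(bad) > 0 && guard < 100L) {
    draws[bad] <- rnorm(length(bad), dist$mean, dist$sd)
    bad <- which(draws <= lo | draws >= hi)
    guard <- guard + 1L
  }
  if (length(bad) > 0) {
    abort_cf("could not draw CBF values inside (0, fps/2).", "bad_dist")
  }
  draws
}

#' Group specification for a synthetic cohort
#'
#' @param label group label, e.g. `"PCD"` or `"HC"`.
#' @param n_subjects number of subjects (`>= 1`).
#' @param recordings_per_subject recordings acquired per subject.
#' @param cbf a [cbf_dist()] for the per-recording true CBF.
#' @return An object of class `cohort_group`.
#' @export
cohort_group <- function(label, n_subjects, recordings_per_subject, cbf) {
  if (n_subjects < 1L) abort_cf("`n_subjects` must be >= 1.", "bad_group")
  if (recordings_per_subject < 1L) {
    abort_cf("`recordings_per_subject` must be >= 1.", "bad_group")
  }
  stopifnot(inherits(cbf, "cbf_dist"))
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 recordings_per_subject = as.integer(recordings_per_subject),
                 cbf = cbf),
            class = "cohort_group")
}

#' Simulate a whole synthetic cohort of recordings
#'
#' Draws a true CBF per recording from each group's distribution and
#' materializes every recording either as a full synthetic image
#' sequence (`output = "stack"`, via [simulate_cilia_stack()]) or as
#' the ROI-mean intensity trace the manual counting route consumes
#' (`output = "trace"`, a fast path that skips frame synthesis: the
#' trace is the in-phase region mean, `offset + amplitude *
#' sin(2 pi f t / fps) + noise / sqrt(area)`).
#'
#' @param groups list of [cohort_group()] specs.
#' @param seed global integer seed. Each recording derives a child
#'   seed `seed + recording index` for its own synthesis, so cohorts
#'   are reproducible and recordings independent.
#' @param fps,n_frames,height,width acquisition envelope passed to the
#'   per-recording simulator.
#' @param amplitude,noise_sigma region beat amplitude and sensor noise
#'   (intensity units). The defaults give a per-pixel spectral SNR
#'   `amplitude^2 / (2 * noise_sigma^2)` of 12.5.
#' @param output `"stack"` or `"trace"`.
#' @param region_radius radius of the centered ciliated disk, px.
#' @param bit_depth quantization of synthesized stacks.
#' @return list with `truth` (tibble `subject, group, recording,
#'   true_cbf_hz, seed`) and `recordings` (named list of
#'   [frame_stack()] or `beat_trace` objects, names matching
#'   `truth$recording`).
#' @export
simulate_cohort <- function(groups, seed = 1L, fps = 500, n_frames = 1000,
                            height = 48, width = 48, amplitude = 20,
                            noise_sigma = 4, output = c("stack", "trace"),
                            region_radius = NULL, bit_depth = 8L) {
  output <- match.arg(output)
  for (g in groups) stopifnot(inherits(g, "cohort_group"))
  region_radius <- region_radius %||% floor(min(height, width) / 3)

  truth <- withr::with_seed(seed, {
    rows <- list()
    rec_counter <- 0L
    for (g in groups) {
      n_rec <- g$n_subjects * g$recordings_per_subject
      f_true <- draw_cbf(g$cbf, n_rec, fps)
      k <- 0L
      for (s in seq_len(g$n_subjects)) {
        for (r in seq_len(g$recordings_per_subject)) {
          k <- k + 1L
          rec_counter <- rec_counter + 1L
          rows[[length(rows) + 1L]] <- tibble(
            subject = sprintf("%s_s%02d", g$label, s),
            group = g$label,
            recording = sprintf("%s_s%02d_r%02d", g$label, s, r),
            true_cbf_hz = f_true[k],
            seed = (seed + rec_counter) %% .Machine$integer.max
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  })

  area <- sum(region_mask(
    sim_region("disk", cbf_hz = 1, amplitude = 1,
               cx = floor((width - 1) / 2), cy = floor((height - 1) / 2),
               radius = region_radius),
    height, width))

  recordings <- lapply(seq_len(nrow(truth)), function(i) {
    f <- truth$true_cbf_hz[i]
    child_seed <- as.integer(truth$seed[i])
    if (output == "stack") {
      cfg <- sim_config(
        fps = fps, n_frames = n_frames, height = height, width = width,
        regions = list(sim_region(
          "disk", cbf_hz = f, amplitude = amplitude,
          cx = floor((width - 1) / 2), cy = floor((height - 1) / 2),
          radius = region_radius)),
        noise_sigma = noise_sigma, bit_depth = bit_depth,
        seed = child_seed)
      simulate_cilia_stack(cfg)$stack
    } else {
      withr::with_seed(child_seed, {
        tvec <- (seq_len(n_frames) - 1) / fps
        vals <- 100 + amplitude * sin(2 * pi * f * tvec)
        if (noise_sigma > 0) {
          vals <- vals + rnorm(n_frames, 0, noise_sigma / sqrt(area))
        }
        beat_trace(vals, fps)
      })
    }
  })
  names(recordings) <- truth$recording
  list(truth = truth, recordings = recordings)
}
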