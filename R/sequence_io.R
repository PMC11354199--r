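#' Sidecar metadata for headerless RAW recordings
#'
#' A RAW recording is a headerless, frame-major, row-major dump of
#' unsigned little-endian samples; everything needed to interpret it
#' lives in a plain-text sidecar of `key: value` lines.
#'
#' @param width,height frame size in pixels.
#' @param bit_depth sample quantization in bits (8 or 16).
#' @param fps frame rate in Hz.
#' @param frame_count number of frames in the payload.
#' @return An object of class `sidecar_meta`.
#' @export
sidecar_meta <- function(width, height, bit_depth, fps, frame_count) {
  fields <- list(width = width, height = height, bit_depth = bit_depth,
                 fps = fps, frame_count = frame_count)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v != round(v)) {
      abort_cf(sprintf("sidecar field `%s` must be a positive integer.", nm),
               "bad_meta")
    }
  }
  if (!bit_depth %in% c(8L, 16L)) {
    abort_cf("RAW sidecar bit_depth must be 8 or 16.", "bad_meta")
  }
  structure(lapply(fields, as.integer), class = "sidecar_meta")
}

read_sidecar <- function(path) {
  if (!file.exists(path)) {
    abort_cf(sprintf("sidecar file not found: %s", path), "missing_sidecar")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  m <- as.list(setNames(vals, keys))
  sidecar_meta(m$width, m$height, m$bit_depth, m$fps, m$frame_count)
}

write_sidecar <- function(meta, path) {
  writeLines(
    sprintf("%s: %d", names(unclass(meta)), unlist(unclass(meta))),
    path
  )
  invisible(path)
}

sidecar_path <- function(raw_path) {
  if (grepl("\\.raw$", raw_path, ignore.case = TRUE)) {
    sub("\\.raw$", ".meta", raw_path, ignore.case = TRUE)
  } else {
    paste0(raw_path, ".meta")
  }
}

infer_dialect <- function(path) {
  if (dir.exists(path)) return("png_seq")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) return("tiff")
  if (grepl("\\.raw$", path, ignore.case = TRUE)) return("raw")
  abort_cf(sprintf("cannot infer sequence dialect from path: %s", path),
           "unknown_dialect")
}

# Rec. 601 luma weights; monochrome cameras make this a degenerate path
# but color inputs must not crash.
luma_collapse <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  ch <- dim(img)[3]
  if (ch == 1L) return(img[, , 1L])
  w <- c(0.299, 0.587, 0.114)
  out <- w[1] * img[, , 1L] + w[2] * img[, , 2L] + w[3] * img[, , 3L]
  out
}

png_bit_depth <- function(file) {
  # bit depth lives at byte 25 of the PNG datastream
  # (8-byte signature + IHDR length/type/width/height)
  hdr <- readBin(file, "raw", n = 25L)
  as.integer(hdr[25L])
}

#' Read a high-speed video image sequence
#'
#' Reads one of the three interchange dialects into a [frame_stack()]:
#' a multipage grayscale TIFF, a directory of numbered PNG frames, or a
#' headerless RAW payload accompanied by a plain-text sidecar. PNG
#' frames are ordered by the numeric suffix of their filenames, not by
#' directory listing order. Color inputs are collapsed to grayscale by
#' standard luma weighting; grayscale integer sources round-trip
#' losslessly.
#'
#' @param path file (TIFF, RAW) or directory (PNG sequence).
#' @param dialect `"tiff"`, `"png_seq"` or `"raw"`; inferred from
#'   `path` when `NULL`.
#' @param fps frame rate in Hz. Required for TIFF and PNG sequences
#'   (neither carries a rate); for RAW it comes from the sidecar.
#' @param meta a [sidecar_meta()] for RAW payloads; when `NULL` the
#'   sidecar file adjacent to `path` (`.meta` extension) is read.
#' @return a [frame_stack()].
#' @examples
#' \donttest{
#' dir <- tempfile()
#' arr <- array(sample(0:255, 16 * 8 * 8, TRUE), dim = c(16, 8, 8))
#' st <- frame_stack(arr, fps = 500)
#' write_sequence(st, dir, "png_seq")
#' st2 <- read_sequence(dir, fps = 500)
#' identical(st$frames, st2$frames)
#' }
#' @export
read_sequence <- function(path, dialect = NULL, fps = NULL, meta = NULL) {
  if (!file.exists(path) && !dir.exists(path)) {
    abort_cf(sprintf("path does not exist: %s", path), "missing_path")
  }
  dialect <- dialect %||% infer_dialect(path)
  switch(
    dialect,
    tiff = read_tiff_stack(path, fps),
    png_seq = read_png_seq(path, fps),
    raw = read_raw_stack(path, meta),
    abort_cf(sprintf("unknown dialect: %s", dialect), "unknown_dialect")
  )
}

read_tiff_stack <- function(path, fps) {
  if (is.null(fps)) {
    abort_cf("`fps` must be supplied for TIFF input (TIFF carries no rate).",
             "missing_fps")
  }
  probe <- tiff::readTIFF(path, info = TRUE)
  bps <- attr(probe, "bits.per.sample") %||% 8L
  if (bps >= 32L) {
    pages <- tiff::readTIFF(path, all = TRUE)
    pages <- lapply(pages, luma_collapse)
    calib <- paste0(path, ".calib")
    if (file.exists(calib)) {
      cv <- read_calib(calib)
      pages <- lapply(pages, function(p) p * cv["scale"] + cv["offset"])
    }
    bit_depth <- 32L
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    pages <- lapply(pages, luma_collapse)
    bit_depth <- as.integer(bps)
  }
  stack_from_pages(pages, fps, bit_depth, "tiff")
}

read_png_seq <- function(path, fps) {
  if (is.null(fps)) {
    abort_cf("`fps` must be supplied for PNG sequences.", "missing_fps")
  }
  files <- list.files(path, pattern = "\\.png$", full.names = TRUE)
  if (length(files) < 2L) {
    abort_cf("PNG sequence needs at least 2 frames.", "bad_sequence")
  }
  suffix <- sub(".*?(\\d+)\\.png$", "\\1", basename(files))
  if (any(suffix == basename(files))) {
    abort_cf("PNG frame filenames must carry a numeric suffix.",
             "bad_sequence")
  }
  files <- files[order(as.integer(suffix))]
  bits <- png_bit_depth(files[[1L]])
  scale <- 2^bits - 1
  pages <- lapply(files, function(f) {
    img <- luma_collapse(png::readPNG(f))
    round(img * scale)
  })
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    abort_cf("inconsistent frame shapes across the PNG sequence.",
             "bad_sequence")
  }
  stack_from_pages(pages, fps, as.integer(bits), "png_seq")
}

read_raw_stack <- function(path, meta) {
  meta <- meta %||% read_sidecar(sidecar_path(path))
  bytes <- if (meta$bit_depth <= 8L) 1L else 2L
  n_samples <- meta$frame_count * meta$width * meta$height
  expected <- n_samples * bytes
  actual <- file.size(path)
  if (actual != expected) {
    abort_cf(sprintf(
      "payload/metadata mismatch: file has %d bytes, sidecar implies %d.",
      actual, expected), "payload_mismatch")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = n_samples, size = bytes,
               signed = FALSE, endian = "little")
  # payload order: frame-major, row-major (x fastest, then y, then t)
  arr <- aperm(array(as.numeric(v),
                     dim = c(meta$width, meta$height, meta$frame_count)),
               c(3L, 2L, 1L))
  frame_stack(arr, fps = meta$fps, bit_depth = meta$bit_depth,
              source_dialect = "raw")
}

stack_from_pages <- function(pages, fps, bit_depth, dialect) {
  d <- dim(pages[[1L]])
  arr <- array(0, dim = c(length(pages), d[1], d[2]))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
  frame_stack(arr, fps = fps, bit_depth = bit_depth,
              source_dialect = dialect)
}

read_calib <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines[nzchar(lines)], ":", fixed = TRUE)
  setNames(as.numeric(trimws(vapply(kv, `[`, "", 2L))),
           trimws(vapply(kv, `[`, "", 1L)))
}

#' Write a high-speed video image sequence
#'
#' Inverse of [read_sequence()]: integer-valued stacks round-trip
#' bit-exactly through every dialect. Float-valued stacks (e.g. the
#' output of [subtract_mean_image()]) are supported by the TIFF dialect
#' only, stored as 32-bit float pages; values outside `[0, 1]` are
#' affinely mapped into range with the calibration recorded in a
#' `.calib` text sidecar that [read_sequence()] inverts.
#'
#' @param stack a [frame_stack()].
#' @param path target file (TIFF, RAW) or directory (PNG sequence).
#' @param dialect `"tiff"`, `"png_seq"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(stack, path, dialect = c("tiff", "png_seq", "raw")) {
  stopifnot(inherits(stack, "frame_stack"))
  dialect <- match.arg(dialect)
  fr <- stack$frames
  integerish <- is_integerish_values(fr) && stack$bit_depth <= 16L
  if (integerish) {
    lim <- 2^stack$bit_depth - 1
    if (min(fr) < 0 || max(fr) > lim) {
      abort_cf(sprintf(
        "intensities exceed declared bit_depth: range [%g, %g] vs [0, %g].",
        min(fr), max(fr), lim), "bit_depth_overflow")
    }
  } else if (dialect != "tiff") {
    abort_cf("float-valued stacks are supported by the tiff dialect only.",
             "float_unsupported")
  }
  switch(
    dialect,
    tiff = write_tiff_stack(stack, path, integerish),
    png_seq = write_png_seq(stack, path),
    raw = write_raw_stack(stack, path)
  )
  invisible(path)
}

write_tiff_stack <- function(stack, path, integerish) {
  d <- dim(stack$frames)
  if (integerish) {
    scale <- 2^stack$bit_depth - 1
    pages <- lapply(seq_len(d[1]), function(t) stack$frames[t, , ] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                    compression = "none", reduce = FALSE)
    calib <- paste0(path, ".calib")
    if (file.exists(calib)) unlink(calib)
  } else {
    lo <- min(stack$frames)
    hi <- max(stack$frames)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(d[1]),
                    function(t) (stack$frames[t, , ] - lo) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
    writeLines(c(sprintf("offset: %.17g", lo),
                 sprintf("scale: %.17g", scale)),
               paste0(path, ".calib"))
  }
  path
}

write_png_seq <- function(stack, path) {
  if (stack$bit_depth > 8L) {
    abort_cf("png_seq dialect writes 8-bit stacks only.", "bit_depth_png")
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  d <- dim(stack$frames)
  for (t in seq_len(d[1])) {
    png::writePNG(stack$frames[t, , ] / 255,
                  file.path(path, sprintf("frame_%06d.png", t)))
  }
  path
}

write_raw_stack <- function(stack, path) {
  d <- dim(stack$frames)
  v <- as.integer(aperm(stack$frames, c(3L, 2L, 1L)))
  con <- file(path, "wb")
  on.exit(close(con))
  if (stack$bit_depth <= 8L) {
    writeBin(as.raw(v), con)
  } else {
    # explicit little-endian unsigned 16-bit to dodge signed overflow
    writeBin(as.raw(rbind(v %% 256L, v %/% 256L)), con)
  }
  write_sidecar(
    sidecar_meta(d[3], d[2], if (stack$bit_depth <= 8L) 8L else 16L,
                 stack$fps, d[1]),
    sidecar_path(path)
  )
  path
}
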