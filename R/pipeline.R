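#' Configuration for a full simulate-analyze-compare run
#'
#' @param simulation list passed to [simulate_cohort()]: `groups`
#'   (list of [cohort_group()]), and optionally `fps`, `n_frames`,
#'   `height`, `width`, `amplitude`, `noise_sigma`, `bit_depth`,
#'   `region_radius`.
#' @param preprocess list of toggles: `rotate` (degrees, default 0),
#'   `roi` (a [rect_roi()] or `NULL`), `stabilize` (logical,
#'   default `FALSE`), `motion_extract` (logical, default `FALSE`;
#'   the spectral route removes per-pixel means regardless).
#' @param analysis list: `n_frames` (`NULL` = all), `band`
#'   (default `c(1, 30)` Hz), `methods` (subset of
#'   `c("manual", "mean_psd", "histogram")`, at least one),
#'   `n_beats` (manual route, default 10).
#' @param stats list: `alpha` (default 0.05).
#' @param seed global integer seed; recordings derive child seeds
#'   from it (see [simulate_cohort()]).
#' @param out_dir optional directory; when given, the cohort table,
#'   report summary (TSV) and run manifest (JSON) are written there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulation, preprocess = list(), analysis = list(),
                       stats = list(), seed = 1L, out_dir = NULL) {
  analysis <- modifyList(
    list(n_frames = NULL, band = c(1, 30),
         methods = c("manual", "mean_psd", "histogram"), n_beats = 10L),
    analysis)
  preprocess <- modifyList(
    list(rotate = 0, roi = NULL, stabilize = FALSE,
         motion_extract = FALSE),
    preprocess)
  stats <- modifyList(list(alpha = 0.05), stats)
  if (length(analysis$methods) < 1L) {
    abort_cf("at least one analysis method is required.", "bad_config")
  }
  bad <- setdiff(analysis$methods, c("manual", "mean_psd", "histogram"))
  if (length(bad)) {
    abort_cf(paste0("unknown analysis method(s): ",
                    paste(bad, collapse = ", ")), "bad_config")
  }
  if (stats$alpha <= 0 || stats$alpha >= 1) {
    abort_cf("`alpha` must be in (0, 1).", "bad_config")
  }
  if (is.null(simulation$groups)) {
    abort_cf("`simulation$groups` is required.", "bad_config")
  }
  structure(list(simulation = simulation, preprocess = preprocess,
                 analysis = analysis, stats = stats,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

preprocess_recording <- function(stack, preprocess) {
  if (preprocess$rotate != 0) {
    stack <- rotate_frames(stack, preprocess$rotate)
  }
  if (!is.null(preprocess$roi)) {
    stack <- crop_roi(stack, preprocess$roi)
  }
  if (isTRUE(preprocess$stabilize)) {
    stack <- stabilize(stack)$stack
  }
  stack
}

# one estimate (or condition object) per configured method; a failing
# method must not take the other methods' results down with it
analyze_recording <- function(stack, analysis, preprocess) {
  stack <- preprocess_recording(stack, preprocess)
  spectral_input <- if (isTRUE(preprocess$motion_extract)) {
    subtract_mean_image(stack)
  } else {
    stack
  }
  out <- list()
  spec <- NULL
  if (any(c("mean_psd", "histogram") %in% analysis$methods)) {
    spec <- tryCatch(
      pixel_power_spectra(spectral_input, n_frames = analysis$n_frames,
                          band = analysis$band),
      error = function(e) e)
  }
  if ("mean_psd" %in% analysis$methods) {
    out$mean_psd <- if (inherits(spec, "error")) spec else
      tryCatch(mean_psd_cbf(spec), error = function(e) e)
  }
  if ("histogram" %in% analysis$methods) {
    out$histogram <- if (inherits(spec, "error")) spec else
      tryCatch(cbf_histogram(dominant_frequency_map(spec))$estimate,
               error = function(e) e)
  }
  if ("manual" %in% analysis$methods) {
    out$manual <- tryCatch({
      trace <- roi_mean_trace(stack)
      n_manual <- min(analysis$n_frames %||% n_frames(stack),
                      n_frames(stack))
      trace <- beat_trace(trace$values[seq_len(n_manual)], trace$fps)
      emulate_manual_count(trace, n_beats = analysis$n_beats)
    }, error = function(e) e)
  }
  out
}

#' Run the full pipeline: simulate, preprocess, analyze, compare
#'
#' Generates a synthetic cohort, analyzes every recording with every
#' configured method under identical frame-count and band settings,
#' assembles the long-format cohort table, and builds the two-cohort
#' comparison report. Per-recording failures are caught, logged in
#' the `failures` table and excluded from the statistics; they are
#' never silently dropped. The run is deterministic given the seed.
#'
#' @param config a [run_config()].
#' @return a list of class `pipeline_run`: `report` (a
#'   [build_report()] result), `table` (cohort table), `truth`
#'   (generator ground truth), `failures` (tibble of caught
#'   per-recording errors), `manifest` (settings echo).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sim_args <- config$simulation
  sim_args$seed <- config$seed
  cohort <- do.call(simulate_cohort, sim_args)

  method_names <- config$analysis$methods
  rows <- list()
  fails <- list()
  for (i in seq_len(nrow(cohort$truth))) {
    rec <- cohort$truth[i, ]
    stack <- cohort$recordings[[rec$recording]]
    res <- tryCatch(
      analyze_recording(stack, config$analysis, config$preprocess),
      error = function(e) e
    )
    for (m in method_names) {
      est <- if (inherits(res, "error")) res else res[[m]]
      if (inherits(est, "error") || inherits(est, "condition")) {
        fails[[length(fails) + 1L]] <- tibble(
          subject = rec$subject, recording = rec$recording,
          method = m, error = conditionMessage(est))
      } else {
        rows[[length(rows) + 1L]] <- tibble(
          subject = rec$subject, group = rec$group,
          recording = rec$recording, method = m,
          cbf_hz = est$value_hz)
      }
    }
  }
  table <- dplyr::bind_rows(rows)
  failures <- if (length(fails)) dplyr::bind_rows(fails) else
    tibble(subject = character(), recording = character(),
           method = character(), error = character())

  # a method that lost a whole group cannot be compared; drop it with
  # a trace in the manifest rather than aborting the cohort
  dropped <- character(0)
  if (nrow(table) > 0) {
    for (m in unique(table$method)) {
      gs <- unique(table$group[table$method == m])
      if (!all(c("PCD", "HC") %in% gs)) dropped <- c(dropped, m)
    }
    table <- table[!table$method %in% dropped, ]
  }
  report <- build_report(table, alpha = config$stats$alpha)

  manifest <- list(
    package = "ciliafreq",
    version = as.character(utils::packageVersion("ciliafreq")),
    seed = config$seed,
    analysis = config$analysis[c("n_frames", "band", "methods",
                                 "n_beats")],
    preprocess = config$preprocess[c("rotate", "stabilize",
                                     "motion_extract")],
    alpha = config$stats$alpha,
    n_recordings = nrow(cohort$truth),
    n_failures = nrow(failures),
    dropped_methods = dropped
  )
  run <- structure(
    list(report = report, table = table, truth = cohort$truth,
         failures = failures, manifest = manifest),
    class = "pipeline_run"
  )
  if (!is.null(config$out_dir)) {
    write_run(run, config$out_dir)
  }
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d recordings, %d failures\n",
              nrow(x$truth), nrow(x$failures)))
  print(x$report)
  invisible(x)
}

write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(run$table, file.path(dir, "cohort_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$report$summary, file.path(dir, "report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
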