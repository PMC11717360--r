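# Orchestration: run configuration, full-pipeline driver, per-subject
# hypnogram summaries and the exclusion report. Every artifact embeds the
# configuration hash and package version so a rerun with the same
# configuration reproduces identical files.

#' Build a run configuration
#'
#' @param band slope fit band, Hz.
#' @param hset IRASA resampling factors.
#' @param epoch_length epoch length in seconds.
#' @param sg_order,sg_frame Savitzky-Golay smoothing parameters.
#' @param min_distance_min,prominence peak detection parameters.
#' @param max_interruption_min,min_nrem_min,min_last_min,min_cycle_min,min_lightening_min
#'   classical cycle rule parameters.
#' @param match_overlap cycle matching threshold (fraction of the shorter
#'   cycle).
#' @param alpha significance level used in prevalence summaries.
#' @param seed integer seed for any stochastic input generation.
#' @return List of class `run_config`.
#' @export
run_config <- function(band = c(0.3, 30), hset = seq(1.1, 1.9, by = 0.05),
                       epoch_length = 30, sg_order = 5, sg_frame = 101,
                       min_distance_min = 20, prominence = 0.9,
                       max_interruption_min = 15, min_nrem_min = 20,
                       min_last_min = 50, min_cycle_min = 110,
                       min_lightening_min = 12, match_overlap = 0.5,
                       alpha = 0.05, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Hash of a run configuration
#'
#' MD5 of the canonical text serialization; embedded in every artifact so
#' outputs can be traced to the configuration that produced them.
#'
#' @param config a [run_config()].
#' @return 32-character hash string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fraccyc ", as.character(utils::packageVersion("fraccyc")),
                    " config ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV artifact written by [run_pipeline()]
#'
#' @param path artifact path.
#' @return The data frame (the stamp comment line is skipped).
#' @export
read_artifact_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Run the full fractal-cycle pipeline on one recording
#'
#' Pipeline order: slope series (computed from EEG, loaded from CSV, or
#' synthesized), fractal cycle detection, classical cycle segmentation with
#' skipped-REM splitting, fractal-classical matching, and a summary report.
#' All outputs are deterministic for a fixed configuration.
#'
#' @param config a [run_config()].
#' @param slopes optional precomputed `slope_series` data frame.
#' @param rec optional single-channel [epoched_recording()] (used with
#'   `hyp` when `slopes` is missing).
#' @param hyp optional [hypnogram()].
#' @param synth optional [synth_spec()]: generate the night instead of
#'   reading inputs (slope series + hypnogram with ground truth).
#' @param out_dir output directory for artifacts; `NULL` skips writing.
#' @param subject subject identifier recorded in the artifacts.
#' @return List of class `pipeline_result`: `$slopes`, `$fractal`
#'   (`fractal_cycles`), `$classical`, `$match`, `$report`, `$hash`, and
#'   `$files` when `out_dir` is given.
#' @export
run_pipeline <- function(config = run_config(), slopes = NULL, rec = NULL,
                         hyp = NULL, synth = NULL, out_dir = NULL,
                         subject = "S1") {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  if (!is.null(synth)) {
    night <- synth_hypnogram(synth)
    hyp <- night$hypnogram
    ss <- synth_slope_series(synth)
    # align the synthesized series with the hypnogram grid
    slopes <- ss$series[ss$series$epoch_index < length(hyp$stages), ,
                        drop = FALSE]
    attr(slopes, "epoch_length") <- synth$epoch_length
  } else if (is.null(slopes)) {
    if (is.null(rec)) stop("provide slopes, rec or synth", call. = FALSE)
    slopes <- slope_time_series(rec, hyp = hyp, band = config$band,
                                hset = config$hset)
  }
  epoch_length <- attr(slopes, "epoch_length")
  if (is.null(epoch_length)) epoch_length <- config$epoch_length

  fractal <- detect_fractal_cycles(
    slopes, epoch_length = epoch_length, sg_order = config$sg_order,
    sg_frame = config$sg_frame, min_distance_min = config$min_distance_min,
    prominence = config$prominence)

  classical <- NULL; match <- NULL
  if (!is.null(hyp)) {
    classical <- segment_cycles(hyp,
                                max_interruption_min = config$max_interruption_min,
                                min_nrem_min = config$min_nrem_min,
                                min_last_min = config$min_last_min)
    classical <- split_skipped(classical, hyp,
                               min_cycle_min = config$min_cycle_min,
                               min_lightening_min = config$min_lightening_min)
    match <- match_cycles(fractal$cycles, classical,
                          min_overlap = config$match_overlap)
  }

  report <- list(
    subject = subject,
    config_hash = hash,
    package_version = as.character(utils::packageVersion("fraccyc")),
    n_fractal_cycles = nrow(fractal$cycles),
    fractal_duration_mean_min = if (nrow(fractal$cycles))
      mean(fractal$cycles$duration_min) else NA,
    descent_mean_z = if (nrow(fractal$cycles))
      mean(fractal$cycles$descent_z) else NA,
    ascent_mean_z = if (nrow(fractal$cycles))
      mean(fractal$cycles$ascent_z) else NA)
  if (!is.null(classical)) {
    report$n_classical_cycles <- nrow(classical)
    report$classical_duration_mean_min <- if (nrow(classical))
      mean(classical$duration_min) else NA
    report$first_cycle_skipped <- if (nrow(classical))
      first_cycle_skipped(classical) else NA
    report$matched_fraction <- match$matched_fraction
    report$one_to_one <- match$one_to_one
    if (nrow(match$pairs) >= 4) {
      sp <- spearman(fractal$cycles$duration_min[match$pairs$fractal_cycle],
                     classical$duration_min[match$pairs$classical_cycle])
      report$matched_duration_spearman <- sp
    }
  }

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      slopes = write_stamped_csv(as.data.frame(slopes),
                                 file.path(out_dir, "slopes.csv"), hash),
      fractal = write_stamped_csv(fractal$cycles,
                                  file.path(out_dir, "fractal_cycles.csv"),
                                  hash))
    if (!is.null(classical)) {
      files <- c(files,
                 classical = write_stamped_csv(
                   classical, file.path(out_dir, "classical_cycles.csv"), hash),
                 matchfile = write_stamped_csv(
                   match$pairs, file.path(out_dir, "match_pairs.csv"), hash))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, report = file.path(out_dir, "report.json"))
  }

  structure(list(slopes = slopes, fractal = fractal, classical = classical,
                 match = match, report = report, hash = hash, files = files),
            class = "pipeline_result")
}

#' Summarize a hypnogram for exclusion screening
#'
#' WASO is computed as wake between sleep onset (first non-wake epoch) and
#' final awakening, as a percentage of that span.
#'
#' @param hyp a [hypnogram()].
#' @return `data.frame(total_recording_min, tst_min, waso_pct,
#'   n_rem_epochs)`.
#' @export
hypnogram_summary <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  el <- hyp$epoch_length
  s <- rules_stages(hyp)
  sleep <- which(s != "WAKE")
  if (!length(sleep)) {
    return(data.frame(total_recording_min = length(s) * el / 60, tst_min = 0,
                      waso_pct = NA_real_, n_rem_epochs = 0L))
  }
  span <- sleep[1]:sleep[length(sleep)]
  data.frame(
    total_recording_min = length(s) * el / 60,
    tst_min = length(sleep) * el / 60,
    waso_pct = 100 * mean(s[span] == "WAKE"),
    n_rem_epochs = sum(s == "REM"))
}

#' Exclusion report for a cohort
#'
#' Flags subjects with more than 25% wake after sleep onset, a total
#' recording shorter than 150 min, or no REM sleep.
#'
#' @param subjects `data.frame` with columns `subject`, `waso_pct`,
#'   `total_recording_min`, `n_rem_epochs` (one row per subject; see
#'   [hypnogram_summary()]).
#' @return The input with `excluded` (logical) and `reason` (";"-joined)
#'   columns appended.
#' @export
exclusion_report <- function(subjects) {
  need <- c("subject", "waso_pct", "total_recording_min", "n_rem_epochs")
  stopifnot(all(need %in% names(subjects)))
  reasons <- lapply(seq_len(nrow(subjects)), function(i) {
    r <- character(0)
    if (isTRUE(subjects$waso_pct[i] > 25)) r <- c(r, "WASO>25%")
    if (subjects$total_recording_min[i] < 150) r <- c(r, "<150 min")
    if (subjects$n_rem_epochs[i] == 0) r <- c(r, "No REM")
    r
  })
  subjects$excluded <- lengths(reasons) > 0
  subjects$reason <- vapply(reasons, paste, character(1), collapse = ";")
  subjects
}
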