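# Epoch grid, channel averaging and hypnogram I/O.
#
# Conventions: epochs are 0-based; intervals are half-open [start, end);
# a duration in minutes is (end - start) * epoch_length / 60.

#' Construct an epoched EEG recording
#'
#' @param samples channels x samples numeric matrix.
#' @param sample_rate sampling rate, Hz.
#' @param epoch_length scoring epoch length in seconds; 20 or 30.
#' @param channel_labels one label per channel.
#' @param artifact_epochs 0-based epoch indices excluded from all automatic
#'   analyses (manually scored artifacts).
#' @param lights_off_epoch,lights_on_epoch 0-based epoch indices bounding the
#'   analysis window; default the full recording.
#' @return An object of class `epoched_recording`.
#' @export
epoched_recording <- function(samples, sample_rate, epoch_length = 30,
                              channel_labels = NULL,
                              artifact_epochs = integer(0),
                              lights_off_epoch = NULL,
                              lights_on_epoch = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  if (!epoch_length %in% c(20, 30)) {
    stop("epoch_length must be 20 or 30 seconds", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("CH", seq_len(nrow(samples)))
  }
  stopifnot(length(channel_labels) == nrow(samples))
  n_epochs <- as.integer(ncol(samples) %/% (epoch_length * sample_rate))
  if (n_epochs < 1) stop("recording shorter than one epoch", call. = FALSE)
  mask <- rep(FALSE, n_epochs)
  artifact_epochs <- as.integer(artifact_epochs)
  if (any(artifact_epochs < 0 | artifact_epochs >= n_epochs)) {
    stop("artifact_epochs outside the epoch grid", call. = FALSE)
  }
  mask[artifact_epochs + 1L] <- TRUE
  structure(list(
    samples = samples,
    sample_rate = sample_rate,
    epoch_length = epoch_length,
    channel_labels = channel_labels,
    n_epochs = n_epochs,
    epoch_artifact_mask = mask,
    lights_off_epoch = if (is.null(lights_off_epoch)) 0L else as.integer(lights_off_epoch),
    lights_on_epoch = if (is.null(lights_on_epoch)) n_epochs else as.integer(lights_on_epoch)
  ), class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat("Epoched EEG recording:", nrow(x$samples), "channel(s) [",
      paste(x$channel_labels, collapse = ", "), "],",
      x$n_epochs, "epochs of", x$epoch_length, "s @", x$sample_rate, "Hz;",
      sum(x$epoch_artifact_mask), "artifact epoch(s)\n")
  invisible(x)
}

#' Average EEG channels into one virtual channel
#'
#' Sample-wise arithmetic mean of the named channels (e.g. F3 and F4); if a
#' channel of a pair was excluded upstream, pass the remaining one alone.
#'
#' @param rec an [epoched_recording()].
#' @param labels channel labels to average; at least one.
#' @return An `epoched_recording` with a single virtual channel.
#' @export
average_channels <- function(rec, labels) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (length(labels) < 1) stop("labels must name at least one channel", call. = FALSE)
  sel <- match(labels, rec$channel_labels)
  if (anyNA(sel)) {
    stop("channel(s) not found: ", paste(labels[is.na(sel)], collapse = ", "),
         "; available: ", paste(rec$channel_labels, collapse = ", "),
         call. = FALSE)
  }
  avg <- colMeans(rec$samples[sel, , drop = FALSE])
  out <- rec
  out$samples <- matrix(avg, nrow = 1)
  out$channel_labels <- paste0("mean(", paste(labels, collapse = ","), ")")
  out
}

#' Default sleep-stage token dictionary
#'
#' Maps common scoring vocabularies onto the canonical [STAGES]: AASM N3 (and
#' legacy S3/S4) map to `SWS`; numeric R&K-style codes are accepted; matching
#' is case-insensitive. `MOVEMENT` is retained as its own stage and merged
#' into `WAKE` only inside the classical cycle rules.
#'
#' @return Named character vector token -> stage.
#' @export
default_stage_map <- function() {
  c(W = "WAKE", WK = "WAKE", WAKE = "WAKE", "0" = "WAKE",
    N1 = "N1", S1 = "N1", "1" = "N1",
    N2 = "N2", S2 = "N2", "2" = "N2",
    N3 = "SWS", S3 = "SWS", S4 = "SWS", SWS = "SWS", "3" = "SWS", "4" = "SWS",
    R = "REM", REM = "REM", "5" = "REM",
    M = "MOVEMENT", MT = "MOVEMENT", MOVEMENT = "MOVEMENT")
}

#' Construct a hypnogram
#'
#' @param stages character vector of stages, one per epoch, values in
#'   [STAGES].
#' @param epoch_length epoch length in seconds.
#' @return Object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_length = 30) {
  bad <- setdiff(unique(stages), STAGES)
  if (length(bad)) {
    stop("invalid stage value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(stages = as.character(stages), epoch_length = epoch_length),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = STAGES))
  cat("Hypnogram:", length(x$stages), "epochs of", x$epoch_length, "s\n")
  print(tab)
  invisible(x)
}

#' Read a hypnogram from a text file
#'
#' Supports a two-column CSV (`epoch,stage`, with or without header) and a
#' one-stage-per-line text file. Stage tokens are translated through a
#' configurable dictionary; an unmapped token is a parse error naming the
#' offending line.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"two_column"` or `"stage_per_line"`.
#' @param stage_map named vector token -> stage; see [default_stage_map()].
#' @param epoch_length epoch length in seconds.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, dialect = c("auto", "two_column", "stage_per_line"),
                           stage_map = default_stage_map(), epoch_length = 30) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("empty hypnogram file: ", path, call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl(",", lines[1])) "two_column" else "stage_per_line"
  }
  if (dialect == "two_column") {
    parts <- strsplit(lines, ",")
    tokens <- trimws(vapply(parts, function(p) p[length(p)], character(1)))
    # tolerate a header row
    if (tolower(tokens[1]) %in% c("stage", "stages")) {
      lines <- lines[-1]; tokens <- tokens[-1]
    }
  } else {
    tokens <- trimws(lines)
  }
  names(stage_map) <- toupper(names(stage_map))
  stages <- unname(stage_map[toupper(tokens)])
  if (anyNA(stages)) {
    bad <- which(is.na(stages))[1]
    stop("unmapped stage token '", tokens[bad], "' at line ", bad,
         " of ", path, call. = FALSE)
  }
  hypnogram(stages, epoch_length = epoch_length)
}

#' Write a hypnogram as a two-column CSV
#'
#' Columns `epoch` (0-based) and `stage` (canonical labels).
#'
#' @param hyp a [hypnogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  df <- data.frame(epoch = seq_along(hyp$stages) - 1L, stage = hyp$stages)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check that a recording and a hypnogram share the epoch grid
#'
#' @param rec an [epoched_recording()].
#' @param hyp a [hypnogram()].
#' @return `TRUE` invisibly; mismatch is a hard error.
#' @export
check_alignment <- function(rec, hyp) {
  stopifnot(inherits(rec, "epoched_recording"), inherits(hyp, "hypnogram"))
  if (rec$epoch_length != hyp$epoch_length) {
    stop("epoch length mismatch: recording ", rec$epoch_length,
         " s vs hypnogram ", hyp$epoch_length, " s", call. = FALSE)
  }
  if (rec$n_epochs != length(hyp$stages)) {
    stop("epoch grid mismatch: recording has ", rec$n_epochs,
         " epochs, hypnogram has ", length(hyp$stages), call. = FALSE)
  }
  invisible(TRUE)
}
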