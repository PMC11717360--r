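# Minimal EDF/EDF+ reader and writer (continuous recordings, EEG use case).
# Header layout per the EDF specification: 256-byte fixed header followed by
# 256 bytes per signal, then int16 little-endian samples grouped by data
# record. Physical values are reconstructed from the per-signal calibration
# (physical/digital min/max).

edf_read_ascii <- function(con, n) {
  trimws(rawToChar(readBin(con, "raw", n = n)))
}

edf_pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) stop("EDF header field too long: '", x, "'", call. = FALSE)
  formatC(x, width = -n)  # left-justified, space padded
}

# format a number to fit an 8-character EDF header field
edf_num8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(signif(x, d), format = "g", digits = d, width = 1)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot represent ", x, " in 8 characters", call. = FALSE)
}

#' Read an EDF/EDF+ file
#'
#' Reads the requested channels of a continuous EDF recording at native
#' sampling rate. All requested channels must share one sampling rate.
#'
#' @param path path to an EDF/EDF+ file.
#' @param channels character vector of channel labels to read; `NULL` reads
#'   all channels.
#' @param epoch_length scoring epoch length in seconds (20 or 30).
#' @param artifact_epochs 0-based indices of epochs to mark as artifact.
#' @return An [epoched_recording()] holding a channels x samples matrix.
#' @export
read_edf <- function(path, channels = NULL, epoch_length = 30,
                     artifact_epochs = integer(0)) {
  con <- file(path, "rb")
  on.exit(close(con))

  version <- edf_read_ascii(con, 8)
  if (!version %in% c("0")) {
    stop("not an EDF file (unrecognized version field '", version, "'): ",
         path, call. = FALSE)
  }
  invisible(readBin(con, "raw", n = 80 + 80 + 8 + 8))  # ids, date, time
  header_bytes <- as.integer(edf_read_ascii(con, 8))
  invisible(readBin(con, "raw", n = 44))
  n_records <- as.integer(edf_read_ascii(con, 8))
  record_dur <- as.numeric(edf_read_ascii(con, 8))
  ns <- as.integer(edf_read_ascii(con, 4))
  if (is.na(ns) || ns < 1 || is.na(n_records) || n_records < 1) {
    stop("unreadable EDF header in ", path, call. = FALSE)
  }

  field <- function(width) {
    vapply(seq_len(ns), function(i) edf_read_ascii(con, width), character(1))
  }
  labels <- field(16)
  invisible(readBin(con, "raw", n = ns * 80))          # transducer
  invisible(readBin(con, "raw", n = ns * 8))           # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  invisible(readBin(con, "raw", n = ns * 80))          # prefiltering
  nsamp <- as.integer(field(8))
  invisible(readBin(con, "raw", n = ns * 32))          # reserved

  if (is.null(channels)) channels <- setdiff(labels, "EDF Annotations")
  sel <- match(channels, labels)
  if (anyNA(sel)) {
    stop("channel(s) not found: ", paste(channels[is.na(sel)], collapse = ", "),
         "; available: ", paste(labels, collapse = ", "), call. = FALSE)
  }
  rates <- nsamp[sel] / record_dur
  if (length(unique(rates)) != 1) {
    stop("requested channels have differing sampling rates: ",
         paste(rates, collapse = ", "), call. = FALSE)
  }

  seek(con, where = header_bytes, origin = "start")
  rec_len <- sum(nsamp)
  raw <- readBin(con, "integer", n = rec_len * n_records, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < rec_len * n_records) {
    stop("EDF file truncated: expected ", rec_len * n_records,
         " samples, got ", length(raw), call. = FALSE)
  }
  offsets <- c(0, cumsum(nsamp))
  out <- matrix(0, nrow = length(sel), ncol = nsamp[sel[1]] * n_records)
  for (j in seq_along(sel)) {
    s <- sel[j]
    idx <- as.vector(outer(seq_len(nsamp[s]) + offsets[s],
                           (seq_len(n_records) - 1) * rec_len, `+`))
    dig <- raw[idx]
    gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
    out[j, ] <- (dig - dig_min[s]) * gain + phys_min[s]
  }

  epoched_recording(out, sample_rate = rates[1], epoch_length = epoch_length,
                    channel_labels = channels,
                    artifact_epochs = artifact_epochs)
}

#' Write a matrix of signals as an EDF file
#'
#' Companion writer used to emit synthetic recordings and to build test
#' fixtures; one-second data records, 16-bit encoding with per-channel
#' calibration spanning the signal range.
#'
#' @param samples channels x samples numeric matrix.
#' @param sample_rate sampling rate in Hz (integer).
#' @param channel_labels one label per row of `samples`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(samples, sample_rate, channel_labels, path) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  ns <- nrow(samples)
  stopifnot(length(channel_labels) == ns, sample_rate == round(sample_rate))
  n_records <- ceiling(ncol(samples) / sample_rate)
  pad <- n_records * sample_rate - ncol(samples)
  if (pad > 0) samples <- cbind(samples, matrix(0, ns, pad))

  phys_min <- apply(samples, 1, min)
  phys_max <- apply(samples, 1, max)
  same <- phys_max - phys_min < .Machine$double.eps
  phys_max[same] <- phys_min[same] + 1
  dig_min <- rep(-32768, ns)
  dig_max <- rep(32767, ns)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) {
    writeChar(paste(vapply(x, edf_pad, character(1), n = width),
                    collapse = ""), con, eos = NULL)
  }
  wr("0", 8)
  wr("synthetic subject", 80)
  wr("synthetic recording", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8)
  wr("", 44)
  wr(n_records, 8)
  wr("1", 8)
  wr(ns, 4)
  wr(channel_labels, 16)
  wr(rep("", ns), 80)
  wr(rep("uV", ns), 8)
  phys_min <- as.numeric(vapply(phys_min, edf_num8, character(1)))
  phys_max <- as.numeric(vapply(phys_max, edf_num8, character(1)))
  bad <- phys_max <= phys_min
  phys_max[bad] <- phys_min[bad] + 1
  wr(vapply(phys_min, edf_num8, character(1)), 8)
  wr(vapply(phys_max, edf_num8, character(1)), 8)
  wr(dig_min, 8)
  wr(dig_max, 8)
  wr(rep("", ns), 80)
  wr(rep(sample_rate, ns), 8)
  wr(rep("", ns), 32)

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1) * sample_rate + 1):(r * sample_rate)
    for (j in seq_len(ns)) {
      dig <- round((samples[j, cols] - phys_min[j]) / gain[j] + dig_min[j])
      writeBin(as.integer(pmin(pmax(dig, dig_min[j]), dig_max[j])), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}
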