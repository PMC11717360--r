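# Fractal cycle detection: z-normalize the slope series, smooth it with a
# Savitzky-Golay filter, find prominent peaks (MATLAB findpeaks semantics),
# and cut peak-to-peak cycles with descent/ascent amplitudes.

#' z-normalize a slope series
#'
#' Within-participant standardization, `(x - mean) / sd`, with the sample
#' standard deviation (n - 1 denominator). Missing values are ignored for
#' the moments and propagated.
#'
#' @param x numeric vector of raw slopes.
#' @return z-scored vector with mean 0 and sample sd 1 over non-missing
#'   entries.
#' @export
znormalize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need at least 2 non-missing values", call. = FALSE)
  s <- stats::sd(x[ok])
  if (s == 0) stop("degenerate series: zero standard deviation", call. = FALSE)
  (x - mean(x[ok])) / s
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with MATLAB `sgolayfilt`
#' transient behavior: interior points are the central Savitzky-Golay
#' convolution, the first and last half-frames come from the polynomial fit
#' over the first/last full frame. Delegates to [signal::sgolayfilt()].
#'
#' @param x numeric vector (no missing values; compact the series first).
#' @param order polynomial order (default 5).
#' @param frame odd frame length in epochs (default 101).
#' @return Smoothed vector, same length as `x`.
#' @export
savgol_smooth <- function(x, order = 5, frame = 101) {
  if (frame %% 2 != 1) stop("frame length must be odd", call. = FALSE)
  if (frame <= order) stop("frame length must exceed polynomial order", call. = FALSE)
  if (anyNA(x)) stop("series contains missing values; compact it first", call. = FALSE)
  if (length(x) < frame) {
    stop("series length (", length(x), ") is shorter than the smoothing frame (",
         frame, "); choose a smaller frame", call. = FALSE)
  }
  as.numeric(signal::sgolayfilt(x, p = order, n = frame))
}

#' Find prominent peaks (MATLAB findpeaks semantics)
#'
#' A peak is a sample strictly greater than its neighbors (a flat top
#' reports its first sample; series endpoints are never peaks). Prominence
#' is the peak height minus the higher of the two flanking minima, each
#' minimum taken between the peak and the nearest higher sample on that side
#' (or the signal border). Peaks below `min_prominence` are removed; then
#' peaks are processed in descending height and any remaining peak closer
#' than `min_distance` to an already accepted one is discarded.
#'
#' @param x numeric vector (smoothed z-scored slopes).
#' @param min_distance minimum index separation between accepted peaks;
#'   peaks exactly `min_distance` apart are kept.
#' @param min_prominence minimum prominence (z units).
#' @return `data.frame(index, height, prominence)` sorted by `index`
#'   (1-based positions in `x`); zero rows if no peak qualifies.
#' @export
find_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  empty <- data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0))
  if (n < 3) return(empty)
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  cand <- which(v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k]) + 1L
  idx <- starts[cand]                     # first sample of each (flat) top
  if (!length(idx)) return(empty)

  prom <- vapply(idx, function(p) {
    h <- x[p]
    j <- p - 1L; lmin <- x[j]
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    j <- p + 1L; rmin <- x[j]
    while (j <= n && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))

  keep <- prom >= min_prominence
  idx <- idx[keep]; prom <- prom[keep]
  if (!length(idx)) return(empty)

  ord <- order(-x[idx], idx)              # tallest first, ties by position
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(idx[accepted] - idx[i]) >= min_distance)) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- accepted[order(idx[accepted])]
  data.frame(index = idx[accepted], height = x[idx[accepted]],
             prominence = prom[accepted])
}

#' Cut fractal cycles between successive peaks
#'
#' A fractal cycle is the interval between two successive prominent peaks of
#' the smoothed slope series; its trough is the series minimum strictly
#' between the peaks, its descent amplitude is trough minus start peak
#' (negative) and its ascent amplitude end peak minus trough (positive).
#'
#' @param peaks `data.frame` from [find_peaks()] (1-based `index` into
#'   `series`).
#' @param series smoothed z-scored slope vector.
#' @param epoch_index 0-based original epoch index for each element of
#'   `series`; durations are computed from these so artifact gaps count
#'   toward elapsed time.
#' @param epoch_length epoch length in seconds.
#' @return `data.frame(cycle, start_epoch, trough_epoch, end_epoch,
#'   duration_min, descent_z, ascent_z)`; zero rows (with a warning) if
#'   fewer than two peaks.
#' @export
extract_cycles <- function(peaks, series, epoch_index = seq_along(series) - 1L,
                           epoch_length = 30) {
  stopifnot(length(series) == length(epoch_index))
  empty <- data.frame(cycle = integer(0), start_epoch = integer(0),
                      trough_epoch = integer(0), end_epoch = integer(0),
                      duration_min = numeric(0), descent_z = numeric(0),
                      ascent_z = numeric(0))
  if (nrow(peaks) < 2) {
    warning("fewer than 2 peaks: no fractal cycles defined", call. = FALSE)
    return(empty)
  }
  p <- sort(peaks$index)
  out <- lapply(seq_len(length(p) - 1L), function(i) {
    a <- p[i]; b <- p[i + 1L]
    interior <- (a + 1L):(b - 1L)
    tr <- interior[which.min(series[interior])]
    data.frame(cycle = i,
               start_epoch = epoch_index[a],
               trough_epoch = epoch_index[tr],
               end_epoch = epoch_index[b],
               duration_min = (epoch_index[b] - epoch_index[a]) * epoch_length / 60,
               descent_z = series[tr] - series[a],
               ascent_z = series[b] - series[tr])
  })
  do.call(rbind, out)
}

#' Detect fractal cycles from a raw slope series
#'
#' End-to-end detector: drop missing slopes (the retained series is treated
#' as contiguous for smoothing and peak finding, while durations use the
#' original epoch grid), z-normalize, Savitzky-Golay smooth, find prominent
#' peaks and cut peak-to-peak cycles. Defaults follow the reference
#' settings: polynomial order 5, frame 101 epochs, minimum peak distance
#' 20 min (40 epochs of 30 s; 60 epochs of 20 s) and minimum prominence
#' 0.9 z.
#'
#' @param slopes a `slope_series` data frame from [slope_time_series()], or
#'   any data frame with `epoch_index` and `slope_raw` columns.
#' @param epoch_length epoch length in seconds; defaults to the series
#'   attribute.
#' @param sg_order,sg_frame Savitzky-Golay parameters.
#' @param min_distance_min minimum peak distance in minutes.
#' @param prominence minimum peak prominence in z units.
#' @return List of class `fractal_cycles`: `$cycles` (see
#'   [extract_cycles()]), `$peaks` (with `epoch_index`), `$series`
#'   (`epoch_index`, `slope_raw`, `slope_z`, `slope_smooth`) and `$params`.
#' @export
detect_fractal_cycles <- function(slopes, epoch_length = NULL, sg_order = 5,
                                  sg_frame = 101, min_distance_min = 20,
                                  prominence = 0.9) {
  if (is.null(epoch_length)) epoch_length <- attr(slopes, "epoch_length")
  if (is.null(epoch_length)) stop("epoch_length not given and not an attribute",
                                  call. = FALSE)
  df <- slopes[!is.na(slopes$slope_raw), , drop = FALSE]
  z <- znormalize(df$slope_raw)
  sm <- savgol_smooth(z, order = sg_order, frame = sg_frame)
  min_dist <- as.integer(round(min_distance_min * 60 / epoch_length))
  pk <- find_peaks(sm, min_distance = min_dist, min_prominence = prominence)
  cyc <- if (nrow(pk) >= 2) {
    extract_cycles(pk, sm, epoch_index = df$epoch_index,
                   epoch_length = epoch_length)
  } else {
    suppressWarnings(extract_cycles(pk, sm, epoch_index = df$epoch_index,
                                    epoch_length = epoch_length))
  }
  pk$epoch_index <- df$epoch_index[pk$index]
  structure(list(
    cycles = cyc,
    peaks = pk,
    series = data.frame(epoch_index = df$epoch_index,
                        slope_raw = df$slope_raw,
                        slope_z = z, slope_smooth = sm),
    params = list(epoch_length = epoch_length, sg_order = sg_order,
                  sg_frame = sg_frame, min_distance_min = min_distance_min,
                  min_distance_epochs = min_dist, prominence = prominence)
  ), class = "fractal_cycles")
}

#' @export
print.fractal_cycles <- function(x, ...) {
  cat("Fractal cycles:", nrow(x$cycles), "cycle(s) from", nrow(x$peaks),
      "peak(s);", nrow(x$series), "retained epochs of",
      x$params$epoch_length, "s\n")
  if (nrow(x$cycles)) print(x$cycles)
  invisible(x)
}

#' Cycle-ordinal overnight profile
#'
#' Group summary of cycle measures by within-subject cycle ordinal (cycle 1,
#' cycle 2, ...): n, mean and sd of duration and of descent/ascent
#' amplitudes, for inspecting the inverted-U overnight shape.
#'
#' @param cycles `data.frame` with columns `subject`, `cycle` and any of
#'   `duration_min`, `descent_z`, `ascent_z`.
#' @return `data.frame` with one row per cycle ordinal.
#' @export
overnight_profile <- function(cycles) {
  stopifnot(all(c("subject", "cycle") %in% names(cycles)))
  vars <- intersect(c("duration_min", "descent_z", "ascent_z"), names(cycles))
  out <- data.frame(cycle = sort(unique(cycles$cycle)))
  out$n <- vapply(out$cycle, function(k) sum(cycles$cycle == k), integer(1))
  for (v in vars) {
    out[[paste0(v, "_mean")]] <- vapply(out$cycle, function(k)
      mean(cycles[[v]][cycles$cycle == k]), numeric(1))
    out[[paste0(v, "_sd")]] <- vapply(out$cycle, function(k)
      stats::sd(cycles[[v]][cycles$cycle == k]), numeric(1))
  }
  out
}
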