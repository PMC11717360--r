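# Per-epoch spectra, IRASA fractal/oscillatory separation, log-log slope.

# Next 5-smooth integer >= n. R's mixed-radix FFT degrades badly on lengths
# with large prime factors; all internal FFT lengths are rounded up to
# products of 2, 3 and 5.
smooth_length <- function(n) as.integer(stats::nextn(n, c(2, 3, 5)))

#' One-sided power spectral density of one epoch
#'
#' Hann-tapered (Welch) estimate. By default a single full-length taper is
#' used so the frequency resolution is at least 1/epoch_length Hz, as needed
#' to fit down to 0.3 Hz; segment averaging with 0.9 fractional overlap is
#' available via `seg_seconds`.
#'
#' @param x numeric vector, one epoch of signal.
#' @param sample_rate sampling rate, Hz.
#' @param seg_seconds Welch segment length in seconds; `NULL` (default) uses
#'   the whole epoch as one segment.
#' @param overlap fractional overlap between Welch segments.
#' @param nfft FFT length; defaults to the next 5-smooth integer at or above
#'   the segment length (zero padding interpolates the spectrum).
#' @return `list(freqs, power)`; power in input-units^2/Hz, such that
#'   `sum(power) * df` approximates the signal variance.
#' @export
compute_psd <- function(x, sample_rate, seg_seconds = NULL, overlap = 0.9,
                        nfft = NULL) {
  n <- length(x)
  if (n < 2) stop("epoch too short for spectral estimation", call. = FALSE)
  seg <- if (is.null(seg_seconds)) n else min(n, round(seg_seconds * sample_rate))
  if (seg < 2) stop("segment shorter than 2 samples", call. = FALSE)
  if (is.null(nfft)) nfft <- smooth_length(seg)
  step <- max(1L, as.integer(round(seg * (1 - overlap))))
  starts <- seq(1L, n - seg + 1L, by = step)

  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg - 1) / (seg - 1))  # Hann
  u <- sum(w^2)                                               # window energy
  nf <- nfft %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg_x <- x[s:(s + seg - 1L)]
    seg_x <- (seg_x - mean(seg_x)) * w
    X <- stats::fft(c(seg_x, numeric(nfft - seg)))
    acc <- acc + Mod(X[1:nf])^2
  }
  p <- acc / (length(starts) * u * sample_rate)
  # one-sided: double everything except DC and (for even nfft) Nyquist
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[nf] <- 1
  list(freqs = (seq_len(nf) - 1) * sample_rate / nfft, power = p * dbl)
}

# Ideal (FFT-domain) resampling of x to m samples over the same duration:
# brick-wall anti-aliasing on downsampling, exact band-limited interpolation
# on upsampling. Equivalent to scipy.signal.resample.
fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(real = numeric(m), imaginary = numeric(m))
  nk <- min(n, m)
  hk <- (nk + 1L) %/% 2L               # DC + strictly positive frequencies
  Y[1:hk] <- X[1:hk]
  nneg <- nk - hk - (if (nk %% 2L == 0L) 1L else 0L)
  if (nneg > 0) Y[(m - nneg + 1L):m] <- X[(n - nneg + 1L):n]
  if (nk %% 2L == 0L) {
    ny <- nk %/% 2L + 1L
    if (m < n) {
      Y[ny] <- X[ny] + X[n - nk %/% 2L + 1L]  # fold the two aliasing bins
    } else {
      Y[ny] <- X[ny] / 2
      Y[m - nk %/% 2L + 1L] <- X[ny] / 2      # split the Nyquist bin
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' IRASA: separate fractal and oscillatory spectral components
#'
#' For each resampling factor h, the epoch is resampled by h and by 1/h
#' (anti-aliased), the PSDs of the pair are computed on the original
#' frequency grid and combined by their geometric mean; narrowband
#' oscillations land at h- and 1/h-shifted frequencies and cancel, while
#' power-law (fractal) spectra are invariant. The fractal component is the
#' median of the geometric means across the h set; the oscillatory residual
#' is total minus fractal.
#'
#' @param x numeric vector, one epoch of signal.
#' @param sample_rate sampling rate, Hz.
#' @param hset resampling factors, all > 1.
#' @param seg_seconds,overlap Welch parameters passed to [compute_psd()].
#'   The default 10 s segments with 0.9 fractional overlap trade a little
#'   spectral resolution for much lower periodogram variance, which keeps
#'   the geometric-mean fractal estimate nearly unbiased relative to the
#'   total spectrum; slope estimates are insensitive to this choice.
#' @return Object of class `epoch_spectrum`:
#'   `list(freqs, total, fractal, oscillatory)`.
#' @export
irasa <- function(x, sample_rate, hset = seq(1.1, 1.9, by = 0.05),
                  seg_seconds = 10, overlap = 0.9) {
  if (any(hset <= 1)) stop("hset values must be > 1", call. = FALSE)
  n <- length(x)
  tot <- compute_psd(x, sample_rate, seg_seconds, overlap)
  geo <- matrix(NA_real_, nrow = length(tot$freqs), ncol = length(hset))
  for (i in seq_along(hset)) {
    h <- hset[i]
    m_up <- smooth_length(round(n * h))
    m_dn <- smooth_length(round(n / h))
    p_up <- compute_psd(fft_resample(x, m_up), sample_rate, seg_seconds, overlap)
    p_dn <- compute_psd(fft_resample(x, m_dn), sample_rate, seg_seconds, overlap)
    up <- stats::approx(p_up$freqs, p_up$power, xout = tot$freqs, rule = 2)$y
    dn <- stats::approx(p_dn$freqs, p_dn$power, xout = tot$freqs, rule = 2)$y
    geo[, i] <- sqrt(up * dn)
  }
  frac <- apply(geo, 1, stats::median)
  structure(list(freqs = tot$freqs, total = tot$power, fractal = frac,
                 oscillatory = tot$power - frac),
            class = "epoch_spectrum")
}

#' Fit the log-log slope of a fractal power spectrum
#'
#' Ordinary least squares of log10(power) on log10(frequency) restricted to
#' a band; the slope estimates the power-law exponent of the aperiodic
#' component (steeper negative slope = relatively more low-frequency power).
#' Nonpositive power bins (possible at spectral edges after the IRASA median)
#' are dropped before taking logs.
#'
#' @param spec an `epoch_spectrum` from [irasa()], or any list with `freqs`
#'   and `fractal` (or `power`) elements.
#' @param band `c(f_lo, f_hi)` in Hz.
#' @return `list(slope, intercept, band, r_squared, n_bins)` of class
#'   `slope_fit`; `intercept` is log10 power at 1 Hz.
#' @export
fit_loglog_slope <- function(spec, band = c(0.3, 30)) {
  stopifnot(length(band) == 2, band[1] < band[2])
  pw <- if (!is.null(spec$fractal)) spec$fractal else spec$power
  keep <- spec$freqs >= band[1] & spec$freqs <= band[2] & pw > 0 &
    is.finite(pw)
  if (sum(keep) < 5) {
    stop("fewer than 5 usable frequency bins in band [", band[1], ", ",
         band[2], "] Hz", call. = FALSE)
  }
  lx <- log10(spec$freqs[keep])
  ly <- log10(pw[keep])
  mx <- mean(lx); my <- mean(ly)
  slope <- sum((lx - mx) * (ly - my)) / sum((lx - mx)^2)
  intercept <- my - slope * mx
  ss_res <- sum((ly - intercept - slope * lx)^2)
  ss_tot <- sum((ly - my)^2)
  structure(list(slope = slope, intercept = intercept, band = band,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n_bins = sum(keep)),
            class = "slope_fit")
}

#' Per-epoch fractal slope time series
#'
#' Runs [irasa()] + [fit_loglog_slope()] on every retained (artifact-free)
#' epoch of a single-channel recording. Epochs whose fit fails are kept with
#' a missing slope rather than silently dropped; artifact epochs are omitted
#' but original epoch indices are preserved in the output so that durations
#' downstream are computed on the original time base.
#'
#' @param rec single-channel [epoched_recording()] (see
#'   [average_channels()]).
#' @param hyp optional [hypnogram()] aligned with `rec`; adds a `stage`
#'   column.
#' @param band fit band in Hz; the default 0.3-30 Hz suits standard sleep
#'   EEG, 0.3-18 Hz suits recordings low-pass filtered near 18 Hz.
#' @param hset IRASA resampling factors.
#' @param seg_seconds,overlap Welch parameters, see [irasa()].
#' @return A `data.frame` of class `slope_series` with columns
#'   `epoch_index` (0-based, original grid), `onset_seconds`, `stage` (if
#'   `hyp` given) and `slope_raw`; attribute `epoch_length`.
#' @export
slope_time_series <- function(rec, hyp = NULL, band = c(0.3, 30),
                              hset = seq(1.1, 1.9, by = 0.05),
                              seg_seconds = 10, overlap = 0.9) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (nrow(rec$samples) != 1) {
    stop("slope_time_series expects a single (averaged) channel; ",
         "see average_channels()", call. = FALSE)
  }
  if (!is.null(hyp)) check_alignment(rec, hyp)
  spe <- rec$epoch_length * rec$sample_rate
  keep <- which(!rec$epoch_artifact_mask) - 1L   # 0-based retained epochs
  keep <- keep[keep >= rec$lights_off_epoch & keep < rec$lights_on_epoch]
  slopes <- vapply(keep, function(e) {
    seg <- rec$samples[1, (e * spe + 1):((e + 1) * spe)]
    tryCatch(fit_loglog_slope(irasa(seg, rec$sample_rate, hset,
                                    seg_seconds = seg_seconds,
                                    overlap = overlap), band)$slope,
             error = function(err) NA_real_)
  }, numeric(1))
  out <- data.frame(epoch_index = keep,
                    onset_seconds = keep * rec$epoch_length,
                    slope_raw = slopes)
  if (!is.null(hyp)) out$stage <- hyp$stages[keep + 1L]
  out <- out[, intersect(c("epoch_index", "onset_seconds", "stage", "slope_raw"),
                         names(out))]
  attr(out, "epoch_length") <- rec$epoch_length
  class(out) <- c("slope_series", "data.frame")
  out
}
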