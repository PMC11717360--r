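# Synthetic nights with known ground truth: hypnogram schedules, colored-
# noise EEG with stage-dependent spectral exponents, and direct slope-series
# synthesis for fast detector tests. All randomness is fixed by the spec's
# seed; the same spec yields bit-identical output.

#' Specification of a synthetic night
#'
#' Defaults emulate a healthy adult night: 4-6 cycles of about 90 min,
#' SWS-heavy early cycles and REM-heavy late ones, a few percent of wake
#' after sleep onset, and stage exponents ordered so wake/REM slopes are
#' flattest and SWS steepest.
#'
#' @param n_cycles number of non-REM - REM cycles.
#' @param cycle_minutes_mean,cycle_minutes_sd cycle duration distribution.
#' @param stage_exponents named vector of spectral exponents beta per stage
#'   (power ~ 1/f^beta); all > 0.
#' @param oscillations data.frame (stage, freq, amplitude) of stage-gated
#'   sinusoids added to the EEG, amplitude relative to the colored-noise sd.
#' @param waso_fraction target fraction of wake inserted after sleep onset.
#' @param skipped_first_prob probability that the first cycle is a long
#'   skipped-REM cycle (> 110 min with a lightening episode between two SWS
#'   blocks).
#' @param epoch_length 20 or 30 s.
#' @param sample_rate EEG sampling rate, Hz.
#' @param slope_peak,slope_trough raw slope levels at fractal-cycle peaks
#'   and troughs for direct slope-series synthesis.
#' @param slope_noise_sd per-epoch Gaussian noise on the synthesized raw
#'   slope series.
#' @param seed integer seed fixing all randomness.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(n_cycles = 5, cycle_minutes_mean = 90,
                       cycle_minutes_sd = 10,
                       stage_exponents = c(WAKE = 1.0, N1 = 1.5, N2 = 2.2,
                                           SWS = 3.0, REM = 1.3,
                                           MOVEMENT = 1.0),
                       oscillations = data.frame(
                         stage = c("WAKE", "N2"),
                         freq = c(10, 13.5),
                         amplitude = c(0.5, 0.4)),
                       waso_fraction = 0.05, skipped_first_prob = 0,
                       epoch_length = 30, sample_rate = 250,
                       slope_peak = -1.1, slope_trough = -3.0,
                       slope_noise_sd = 0.25, seed = 1) {
  if (any(stage_exponents <= 0)) stop("stage exponents must be > 0", call. = FALSE)
  if (waso_fraction < 0 || waso_fraction > 1 ||
      skipped_first_prob < 0 || skipped_first_prob > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_cycles < 1) stop("need at least one cycle", call. = FALSE)
  if (cycle_minutes_mean - 3 * cycle_minutes_sd < 35) {
    stop("cycle duration distribution reaches below 35 min; infeasible for ",
         "the >= 20 min non-REM rule", call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_spec")
}

to_epochs <- function(minutes, epoch_length) {
  as.integer(round(minutes * 60 / epoch_length))
}

# inverted-U ordinal modulation of cycle durations (mid-night cycles longest)
ordinal_profile <- function(k) {
  if (k == 1) return(1)
  x <- seq(0, 1, length.out = k)
  0.92 + 0.16 * (1 - (2 * x - 1)^2)
}

#' Generate a synthetic hypnogram with ground truth
#'
#' Builds `n_cycles` cycles of N1 - N2 - SWS - N2 - REM with sampled
#' durations (SWS shrinking and REM growing across the night), optional
#' skipped-REM first cycle, short WASO bouts after the first cycle, and
#' leading/trailing wake. The planted cycle boundaries follow the classical
#' convention (a cycle ends with the end of its REM episode).
#'
#' @param spec a [synth_spec()].
#' @return `list(hypnogram, truth)`; `truth` holds the planted cycle table
#'   (`start_epoch`, `end_epoch`, `skipped`) and the stage schedule.
#' @export
synth_hypnogram <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  el <- spec$epoch_length
  k <- spec$n_cycles
  prof <- ordinal_profile(k)
  durs <- pmax(45, pmin(108, stats::rnorm(k, spec$cycle_minutes_mean * prof,
                                          spec$cycle_minutes_sd)))
  skipped_first <- stats::runif(1) < spec$skipped_first_prob

  stages <- rep("WAKE", to_epochs(5, el))          # lights off, pre-sleep wake
  truth <- list()
  for (i in seq_len(k)) {
    if (i == 1 && skipped_first) {
      # long first cycle: SWS blocks flanking a >= 12 min lightening, > 110 min
      d <- max(durs[1], 120)
      rem <- 12
      light <- 14
      n1 <- 3
      sws1 <- 0.32 * (d - rem - light - n1 - 16)
      sws2 <- 0.28 * (d - rem - light - n1 - 16)
      n2a <- 8
      n2b <- d - rem - light - n1 - sws1 - sws2 - n2a
      seg <- c(N1 = n1, N2 = n2a, SWS = sws1, N2 = light, SWS = sws2,
               N2 = n2b, REM = rem)
    } else {
      d <- durs[i]
      frac <- (i - 1) / max(1, k - 1)
      rem <- 10 + 15 * frac                         # REM grows over night
      sws <- max(4, (d - rem) * (0.45 - 0.38 * frac))  # SWS shrinks
      n1 <- if (i == 1) 2 else 1
      n2a <- max(6, 0.45 * (d - rem - sws - n1))
      n2b <- d - rem - sws - n1 - n2a
      seg <- c(N1 = n1, N2 = n2a, SWS = sws, N2 = n2b, REM = rem)
    }
    seg_ep <- to_epochs(seg, el)
    start <- length(stages)                         # 0-based cycle start
    stages <- c(stages, rep(names(seg), seg_ep))
    truth[[i]] <- data.frame(cycle = i, start_epoch = start,
                             end_epoch = length(stages),
                             skipped = i == 1 && skipped_first)
  }
  # short WASO bouts (1-2 epochs) replacing N2 after the first cycle
  n_waso <- round(spec$waso_fraction * length(stages) / 1.5)
  if (n_waso > 0) {
    eligible <- which(stages == "N2")
    eligible <- eligible[eligible > truth[[1]]$end_epoch]
    # keep bouts short and apart so they never form a lightening episode
    if (length(eligible)) {
      at <- sort(sample(eligible, min(n_waso, length(eligible))))
      at <- at[c(TRUE, diff(at) > 4)]
      stages[at] <- "WAKE"
    }
  }
  stages <- c(stages, rep("N2", to_epochs(4, el)),  # brief post-REM sleep tail
              rep("WAKE", to_epochs(5, el)))
  truth_df <- do.call(rbind, truth)
  list(hypnogram = hypnogram(stages, epoch_length = el),
       truth = list(cycles = truth_df, stages = stages,
                    skipped_first = skipped_first))
}

# colored noise with power ~ 1/f^beta via inverse-FFT spectral shaping with
# random phases; unit variance.
colored_noise <- function(n, beta, sample_rate) {
  nf <- n %/% 2
  f <- seq_len(nf) * sample_rate / n
  amp <- f^(-beta / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  pos <- amp * exp(1i * ph)
  if (n %% 2 == 0) pos[nf] <- Re(pos[nf])     # real Nyquist bin
  spec <- c(0, pos, Conj(rev(pos[seq_len(nf - (1 - n %% 2))])))
  x <- Re(stats::fft(spec, inverse = TRUE))
  x / stats::sd(x)
}

#' Synthesize EEG for a hypnogram
#'
#' Per epoch: colored noise whose spectral exponent follows the stage
#' (`spec$stage_exponents`) plus stage-gated sinusoidal oscillations; epoch
#' joins are blended with a half-second raised-cosine crossfade so the
#' signal stays amplitude-continuous.
#'
#' @param spec a [synth_spec()].
#' @param hyp the [hypnogram()] to sonify, typically from
#'   [synth_hypnogram()].
#' @return Single-channel [epoched_recording()].
#' @export
synth_eeg <- function(spec, hyp) {
  stopifnot(inherits(spec, "synth_spec"), inherits(hyp, "hypnogram"))
  set.seed(spec$seed + 1L)
  fs <- spec$sample_rate
  el <- spec$epoch_length
  spe <- el * fs
  ne <- length(hyp$stages)
  xfade <- fs %/% 2
  w_in <- 0.5 - 0.5 * cos(pi * seq(0, 1, length.out = xfade)) # rising half
  out <- numeric(ne * spe)
  prev_tail <- NULL
  for (e in seq_len(ne)) {
    st <- hyp$stages[e]
    beta <- spec$stage_exponents[[st]]
    x <- colored_noise(spe + xfade, beta, fs)
    osc <- spec$oscillations[spec$oscillations$stage == st, , drop = FALSE]
    if (nrow(osc)) {
      tt <- seq_len(spe + xfade) / fs
      for (j in seq_len(nrow(osc))) {
        x <- x + osc$amplitude[j] *
          sin(2 * pi * osc$freq[j] * tt + stats::runif(1, 0, 2 * pi))
      }
    }
    if (!is.null(prev_tail)) {
      x[seq_len(xfade)] <- w_in * x[seq_len(xfade)] + (1 - w_in) * prev_tail
    }
    out[((e - 1) * spe + 1):(e * spe)] <- x[seq_len(spe)]
    prev_tail <- x[(spe + 1):(spe + xfade)]
  }
  epoched_recording(matrix(out, nrow = 1), sample_rate = fs,
                    epoch_length = el, channel_labels = "SYNTH")
}

#' Synthesize a raw fractal-slope series directly
#'
#' Fast path for detector tests: plants `n_cycles + 1` peaks at the raw
#' level `spec$slope_peak`, connected by cosine descent-ascent arcs down to
#' troughs near `spec$slope_trough` (shallowing over the night), with a
#' short lead-in ascent and tail descent so the first and last peaks have
#' full prominence, plus per-epoch Gaussian noise.
#'
#' @param spec a [synth_spec()]; `n_cycles` cycles means `n_cycles + 1`
#'   planted peaks.
#' @return `list(series, truth)`; `series` is a `slope_series` data frame,
#'   `truth` holds planted peak/trough epochs and cycle durations (min).
#' @export
synth_slope_series <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed + 2L)
  el <- spec$epoch_length
  k <- spec$n_cycles
  prof <- ordinal_profile(k)
  durs <- pmax(45, pmin(108, stats::rnorm(k, spec$cycle_minutes_mean * prof,
                                          spec$cycle_minutes_sd)))
  dep <- to_epochs(durs, el)
  # long enough that edge peaks clear the Savitzky-Golay startup transient
  lead <- to_epochs(30, el)
  peaks <- lead + c(0L, cumsum(dep))                # 0-based peak epochs
  n <- peaks[length(peaks)] + lead + 1L
  m <- numeric(n)
  pk <- spec$slope_peak
  # lead-in: rise from a shallow trough to the first peak
  m[1:(lead + 1)] <- pk - 1.4 * (1 + cos(pi * seq(0, 1, length.out = lead + 1))) / 2
  troughs <- integer(k)
  for (i in seq_len(k)) {
    a <- peaks[i]; b <- peaks[i + 1]
    depth <- (pk - spec$slope_trough) * (1 - 0.12 * (i - 1) / max(1, k - 1))
    idx <- a:b
    m[idx + 1L] <- pk - depth * (1 - cos(2 * pi * (idx - a) / (b - a))) / 2
    troughs[i] <- a + as.integer(round((b - a) / 2))
  }
  tail_idx <- (peaks[k + 1] + 1):(n - 1)
  m[tail_idx + 1L] <- pk - 1.4 *
    (1 - cos(pi * (tail_idx - peaks[k + 1]) / lead)) / 2
  raw <- m + stats::rnorm(n, 0, spec$slope_noise_sd)
  series <- data.frame(epoch_index = 0:(n - 1),
                       onset_seconds = (0:(n - 1)) * el,
                       slope_raw = raw)
  attr(series, "epoch_length") <- el
  class(series) <- c("slope_series", "data.frame")
  list(series = series,
       truth = list(peak_epochs = peaks, trough_epochs = troughs,
                    duration_min = dep * el / 60, mean_level = m))
}
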