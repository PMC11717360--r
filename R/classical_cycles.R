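# Classical non-REM - REM cycle segmentation from hypnograms, with adapted
# Feinberg & Floyd rules: a cycle starts with N1/N2 (sometimes wake), needs
# >= 20 min of N2/SWS before its terminating REM episode, and ends with the
# end of that REM episode. Long (> 110 min) cycles containing a qualifying
# "lightening of sleep" are split into a skipped-REM cycle plus remainder;
# a final REM-less segment is kept as an incomplete cycle only if > 50 min.
#
# MOVEMENT epochs are treated as WAKE inside these rules.

rules_stages <- function(hyp) {
  s <- hyp$stages
  s[s == "MOVEMENT"] <- "WAKE"
  s
}

run_table <- function(stages) {
  r <- rle(stages)
  ends <- cumsum(r$lengths)
  data.frame(stage = r$values,
             start = ends - r$lengths,      # 0-based
             end = ends,                    # half-open
             len = r$lengths)
}

#' Find REM episodes in a hypnogram
#'
#' Maximal runs of REM merged across interruptions (wake or short non-REM
#' segments) shorter than `max_interruption_min`; each episode begins and
#' ends with REM epochs. No minimum REM duration is applied.
#'
#' @param hyp a [hypnogram()].
#' @param max_interruption_min interruptions at or above this many minutes
#'   terminate an episode (default 15).
#' @return `data.frame(start_epoch, end_epoch, rem_minutes)` with 0-based
#'   half-open epoch intervals; `rem_minutes` is the episode span (including
#'   brief interruptions).
#' @export
find_rem_episodes <- function(hyp, max_interruption_min = 15) {
  stopifnot(inherits(hyp, "hypnogram"))
  el <- hyp$epoch_length
  runs <- run_table(rules_stages(hyp))
  rem <- runs[runs$stage == "REM", , drop = FALSE]
  if (!nrow(rem)) {
    return(data.frame(start_epoch = integer(0), end_epoch = integer(0),
                      rem_minutes = numeric(0)))
  }
  starts <- rem$start[1]; ends <- rem$end[1]
  if (nrow(rem) > 1) {
    for (i in 2:nrow(rem)) {
      gap_min <- (rem$start[i] - ends[length(ends)]) * el / 60
      if (gap_min < max_interruption_min) {
        ends[length(ends)] <- rem$end[i]
      } else {
        starts <- c(starts, rem$start[i])
        ends <- c(ends, rem$end[i])
      }
    }
  }
  data.frame(start_epoch = starts, end_epoch = ends,
             rem_minutes = (ends - starts) * el / 60)
}

#' Segment classical sleep cycles from a hypnogram
#'
#' Cycle k starts at the first sleep-eligible epoch after cycle k-1's end
#' (or at sleep onset) and ends with the end of its terminating REM episode,
#' which must be preceded by at least `min_nrem_min` cumulative minutes of
#' N2/SWS within the cycle (a REM episode arriving earlier, e.g. sleep-onset
#' REM, is absorbed into the ongoing cycle). The final REM-less segment is
#' kept as an incomplete cycle only if longer than `min_last_min` minutes;
#' shorter tails are dropped and reported in the `dropped_tail_min`
#' attribute.
#'
#' @param hyp a [hypnogram()].
#' @param max_interruption_min passed to [find_rem_episodes()].
#' @param min_nrem_min minimum cumulative N2+SWS before REM termination
#'   (default 20).
#' @param min_last_min threshold for keeping the final incomplete cycle
#'   (default 50; strictly greater-than).
#' @return `data.frame(cycle, start_epoch, end_epoch, duration_min,
#'   rem_minutes, skipped, complete)`; zero rows with a message attribute if
#'   the hypnogram contains no sleep.
#' @export
segment_cycles <- function(hyp, max_interruption_min = 15, min_nrem_min = 20,
                           min_last_min = 50) {
  stopifnot(inherits(hyp, "hypnogram"))
  el <- hyp$epoch_length
  s <- rules_stages(hyp)
  n <- length(s)
  empty <- data.frame(cycle = integer(0), start_epoch = integer(0),
                      end_epoch = integer(0), duration_min = numeric(0),
                      rem_minutes = numeric(0), skipped = logical(0),
                      complete = logical(0))
  sleep <- which(s != "WAKE")
  if (!length(sleep)) {
    attr(empty, "diagnostic") <- "no sleep epochs in hypnogram"
    return(empty)
  }
  onset <- sleep[1] - 1L                       # 0-based sleep onset
  final_sleep_end <- sleep[length(sleep)]      # half-open end of sleep period
  eps <- find_rem_episodes(hyp, max_interruption_min)

  cycles <- list()
  start <- onset
  for (i in seq_len(nrow(eps))) {
    if (eps$start_epoch[i] < start) next       # inside a previous cycle
    nrem_min <- if (eps$start_epoch[i] > start) {
      # epochs start .. ep_start-1 (0-based), i.e. 1-based start+1 .. ep_start
      sum(s[(start + 1L):eps$start_epoch[i]] %in% c("N2", "SWS")) * el / 60
    } else 0
    if (nrem_min < min_nrem_min) next          # absorbed (e.g. early REM)
    cycles[[length(cycles) + 1L]] <- data.frame(
      start_epoch = start, end_epoch = eps$end_epoch[i],
      rem_minutes = eps$rem_minutes[i], skipped = FALSE, complete = TRUE)
    start <- eps$end_epoch[i]                  # next eligible epoch
  }

  dropped_tail <- 0
  if (start < final_sleep_end) {
    tail_min <- (final_sleep_end - start) * el / 60
    if (tail_min > min_last_min) {
      cycles[[length(cycles) + 1L]] <- data.frame(
        start_epoch = start, end_epoch = final_sleep_end,
        rem_minutes = 0, skipped = FALSE, complete = FALSE)
    } else {
      dropped_tail <- tail_min
    }
  }
  if (!length(cycles)) {
    attr(empty, "diagnostic") <- "no classical cycle could be formed"
    attr(empty, "dropped_tail_min") <- dropped_tail
    return(empty)
  }
  out <- do.call(rbind, cycles)
  out$duration_min <- (out$end_epoch - out$start_epoch) * el / 60
  out <- data.frame(cycle = seq_len(nrow(out)),
                    out[c("start_epoch", "end_epoch", "duration_min",
                          "rem_minutes", "skipped", "complete")])
  attr(out, "dropped_tail_min") <- dropped_tail
  out
}

# Locate a qualifying "lightening of sleep" inside one long cycle:
# a maximal run of light stages (wake/N1/N2/movement) of at least
# min_lightening_min minutes that is either flanked by SWS on both sides
# (preferred) or starts in the middle third of the cycle. Returns the
# 0-based start epoch of the run, or NA.
find_lightening <- function(stages01, cycle_start, cycle_end,
                            min_lightening_min, epoch_length) {
  seg <- stages01[(cycle_start + 1L):cycle_end]
  runs <- run_table(seg)
  runs$start <- runs$start + cycle_start
  runs$end <- runs$end + cycle_start
  light <- runs$stage %in% c("WAKE", "N1", "N2")
  long_enough <- runs$len * epoch_length / 60 >= min_lightening_min
  cand <- which(light & long_enough)
  if (!length(cand)) return(NA_integer_)
  sws_runs <- runs[runs$stage == "SWS", , drop = FALSE]
  flanked <- vapply(cand, function(i) {
    any(sws_runs$end <= runs$start[i]) && any(sws_runs$start >= runs$end[i])
  }, logical(1))
  third <- (cycle_end - cycle_start) / 3
  middle <- runs$start[cand] >= cycle_start + third &
    runs$start[cand] < cycle_end - third
  ok <- cand[flanked]
  if (!length(ok)) ok <- cand[middle]
  if (!length(ok)) return(NA_integer_)
  runs$start[ok[1]]
}

#' Split long cycles containing a skipped REM episode
#'
#' Cycles longer than `min_cycle_min` (default 110) minutes are split in two
#' at the start of a qualifying lightening of sleep: a continuous episode of
#' wake/N1/N2/movement of at least `min_lightening_min` (default 12) minutes
#' that is flanked by slow-wave sleep, or that starts in the middle third of
#' the cycle. The REM-less first half is flagged `skipped`; at most one
#' split per long cycle, and a split is only accepted if both halves are at
#' least `min_lightening_min` long.
#'
#' @param cycles output of [segment_cycles()].
#' @param hyp the [hypnogram()] the cycles were segmented from.
#' @param min_cycle_min only cycles strictly longer than this are candidates.
#' @param min_lightening_min minimum lightening episode duration, minutes.
#' @return Re-numbered cycle `data.frame` with updated `skipped` flags.
#' @export
split_skipped <- function(cycles, hyp, min_cycle_min = 110,
                          min_lightening_min = 12) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (!nrow(cycles)) return(cycles)
  el <- hyp$epoch_length
  s <- rules_stages(hyp)
  pieces <- list()
  for (i in seq_len(nrow(cycles))) {
    cy <- cycles[i, ]
    split_at <- NA_integer_
    if (cy$duration_min > min_cycle_min) {
      split_at <- find_lightening(s, cy$start_epoch, cy$end_epoch,
                                  min_lightening_min, el)
      if (!is.na(split_at)) {
        left_min <- (split_at - cy$start_epoch) * el / 60
        right_min <- (cy$end_epoch - split_at) * el / 60
        if (left_min < min_lightening_min || right_min < min_lightening_min) {
          split_at <- NA_integer_
        }
      }
    }
    if (is.na(split_at)) {
      pieces[[length(pieces) + 1L]] <- cy
    } else {
      first <- cy; second <- cy
      first$end_epoch <- split_at
      first$rem_minutes <- 0
      first$skipped <- TRUE
      second$start_epoch <- split_at
      pieces[[length(pieces) + 1L]] <- first
      pieces[[length(pieces) + 1L]] <- second
    }
  }
  out <- do.call(rbind, pieces)
  out$duration_min <- (out$end_epoch - out$start_epoch) * el / 60
  out$cycle <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "dropped_tail_min") <- attr(cycles, "dropped_tail_min")
  out
}

#' Is the first classical cycle a skipped-REM cycle?
#'
#' @param cycles cycle `data.frame` with a `skipped` column (after
#'   [split_skipped()]).
#' @return `TRUE` iff the first cycle is flagged skipped.
#' @export
first_cycle_skipped <- function(cycles) {
  if (!nrow(cycles)) stop("no cycles", call. = FALSE)
  isTRUE(cycles$skipped[order(cycles$start_epoch)][1])
}
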