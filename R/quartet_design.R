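#' Frame timing of the apparent-motion quartet
#'
#' The quartet flashes a pair of diagonally opposite inducers for a fixed
#' number of display frames, followed by a blank inter-stimulus gap; one
#' full apparent-motion cycle comprises `pairs_per_cycle` pair
#' presentations. Defaults reproduce the experimental timing: 9 frames on
#' (150 ms at 60 Hz), 4 frames gap (67 ms), two pair presentations per
#' cycle.
#'
#' @param refresh_hz Display refresh rate (Hz).
#' @param pair_on_frames Frames per inducer-pair presentation.
#' @param isi_frames Frames per inter-stimulus gap.
#' @param pairs_per_cycle Pair presentations per apparent-motion cycle.
#' @return A `stimulus_timing` list.
#' @export
stimulus_timing <- function(refresh_hz = 60, pair_on_frames = 9,
                            isi_frames = 4, pairs_per_cycle = 2) {
  counts <- c(pair_on_frames, isi_frames, pairs_per_cycle)
  if (refresh_hz <= 0 || any(counts <= 0) || any(counts != round(counts))) {
    stop("invalid timing: frame counts must be positive integers and refresh_hz > 0",
         call. = FALSE)
  }
  structure(list(refresh_hz = refresh_hz,
                 pair_on_frames = as.integer(pair_on_frames),
                 isi_frames = as.integer(isi_frames),
                 pairs_per_cycle = as.integer(pairs_per_cycle)),
            class = "stimulus_timing")
}

#' Apparent-motion cycle frequency
#'
#' Frequency of the full apparent-motion cycle implied by the frame timing:
#' `refresh_hz / (pairs_per_cycle * (pair_on_frames + isi_frames))`,
#' rounded to `digits` decimals for display (the conventionally reported value
#' is one decimal: 2.3 Hz at the default timing).
#'
#' @param timing A [stimulus_timing()] object.
#' @param digits Decimals for the display rounding (NULL for unrounded).
#' @return Cycle frequency in Hz.
#' @export
cycle_frequency <- function(timing, digits = 1) {
  stopifnot(inherits(timing, "stimulus_timing"))
  f <- timing$refresh_hz /
    (timing$pairs_per_cycle * (timing$pair_on_frames + timing$isi_frames))
  if (is.null(digits)) f else round(f, digits)
}

quartet_conditions <- c("fixation", "horizontal", "vertical", "flicker", "ambiguous")

new_events <- function(onset, duration, trial_type, source) {
  data.frame(onset = onset, duration = duration,
             trial_type = trial_type, source = source,
             stringsAsFactors = FALSE)
}

#' Validate an events table
#'
#' Checks the invariants of the BIDS-dialect events tables used throughout:
#' non-decreasing onsets, positive durations, labels from the closed
#' condition set, and no overlap between events of the same source.
#'
#' @param events Data frame with columns onset, duration, trial_type, source.
#' @return `events`, invisibly, after validation.
#' @export
validate_events <- function(events) {
  req <- c("onset", "duration", "trial_type", "source")
  if (!all(req %in% names(events))) {
    stop("events table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(events$duration <= 0)) stop("event durations must be > 0", call. = FALSE)
  if (any(events$onset < 0)) stop("event onsets must be >= 0", call. = FALSE)
  bad <- setdiff(unique(events$trial_type), quartet_conditions)
  if (length(bad)) stop("unknown condition label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (src in unique(events$source)) {
    e <- events[events$source == src, ]
    e <- e[order(e$onset), ]
    if (is.unsorted(e$onset)) stop("onsets must be non-decreasing", call. = FALSE)
    if (nrow(e) > 1L) {
      ends <- e$onset + e$duration
      if (any(e$onset[-1L] < ends[-nrow(e)] - 1e-9)) {
        stop("overlapping events within source '", src, "'", call. = FALSE)
      }
    }
  }
  invisible(events)
}

build_block_events <- function(motion_block_s, alternations, flicker_s,
                               repetitions, fixation_s, fixation_both_ends,
                               ambiguous, start = "horizontal") {
  if (any(c(motion_block_s, flicker_s, repetitions, alternations) <= 0) ||
      fixation_s < 0) {
    stop("invalid schedule: durations and repetitions must be positive",
         call. = FALSE)
  }
  pair <- if (start == "horizontal") c("horizontal", "vertical")
          else c("vertical", "horizontal")
  super <- if (ambiguous) {
    list(conds = c("ambiguous", "flicker"),
         durs = c(2 * alternations * motion_block_s, flicker_s))
  } else {
    list(conds = c(rep(pair, alternations), "flicker"),
         durs = c(rep(motion_block_s, 2 * alternations), flicker_s))
  }
  conds <- rep(super$conds, repetitions)
  durs <- rep(super$durs, repetitions)
  if (fixation_s > 0) {
    conds <- c("fixation", conds)
    durs <- c(fixation_s, durs)
    if (fixation_both_ends) {
      conds <- c(conds, "fixation")
      durs <- c(durs, fixation_s)
    }
  }
  new_events(cumsum(c(0, durs[-length(durs)])), durs, conds, "stimulus")
}

#' Build the physical motion-quartet run schedule
#'
#' One super-block is four alternations of 10-s horizontal and 10-s
#' vertical motion (80 s) followed by a 16-s flicker baseline; the scheme
#' repeats six times, with a 20-s fixation bookend at each end. The number
#' of volumes is the floor of the total duration over the TR.
#'
#' @param motion_block_s Duration of each motion block (s).
#' @param alternations Horizontal/vertical alternations per super-block.
#' @param flicker_s Flicker baseline duration (s).
#' @param repetitions Super-block repetitions per run.
#' @param fixation_s Fixation bookend duration (s).
#' @param fixation_both_ends Fixation at both start and end (default) or
#'   start only.
#' @param tr_s Repetition time (s).
#' @param start First motion condition of each super-block ("horizontal"
#'   or "vertical"); counterbalanced across runs in cohort simulation.
#' @return List with `events` (stimulus-source events table), `tr_s`,
#'   `n_volumes`, and `total_s`.
#' @export
build_physical_schedule <- function(motion_block_s = 10, alternations = 4,
                                    flicker_s = 16, repetitions = 6,
                                    fixation_s = 20, fixation_both_ends = TRUE,
                                    tr_s = 2, start = "horizontal") {
  ev <- build_block_events(motion_block_s, alternations, flicker_s,
                           repetitions, fixation_s, fixation_both_ends,
                           ambiguous = FALSE, start = start)
  validate_events(ev)
  total <- sum(ev$duration)
  list(events = ev, tr_s = tr_s, n_volumes = as.integer(floor(total / tr_s)),
       total_s = total)
}

#' Percept-switch process for the ambiguous quartet
#'
#' Dwell times between perceptual switches are drawn from a gamma
#' distribution truncated to `[min_dwell_s, max_dwell_s]`. The defaults
#' (mean 6 s, shape 3, bounds 3-20 s) give the right-skewed dwell
#' distribution typical of bistable perception while respecting the
#' observed 3-20 s range.
#'
#' @param min_dwell_s,max_dwell_s Truncation bounds (s).
#' @param mean_dwell_s Mean of the untruncated gamma (s).
#' @param shape Gamma shape parameter.
#' @return A `percept_process` list.
#' @export
percept_process <- function(min_dwell_s = 3, max_dwell_s = 20,
                            mean_dwell_s = 6, shape = 3) {
  if (!(min_dwell_s > 0 && min_dwell_s < max_dwell_s)) {
    stop("invalid process: need 0 < min_dwell_s < max_dwell_s", call. = FALSE)
  }
  stopifnot(mean_dwell_s > 0, shape > 0)
  structure(list(min_dwell_s = min_dwell_s, max_dwell_s = max_dwell_s,
                 mean_dwell_s = mean_dwell_s, shape = shape),
            class = "percept_process")
}

#' Sample truncated-gamma percept dwell times
#'
#' Inverse-CDF sampling restricted to the truncation interval (so every
#' draw is within bounds by construction).
#'
#' @param process A [percept_process()].
#' @param n Number of dwells.
#' @return Numeric vector of dwell times (s).
#' @export
sample_dwells <- function(process, n) {
  rate <- process$shape / process$mean_dwell_s
  lo <- stats::pgamma(process$min_dwell_s, shape = process$shape, rate = rate)
  hi <- stats::pgamma(process$max_dwell_s, shape = process$shape, rate = rate)
  u <- stats::runif(n, lo, hi)
  stats::qgamma(u, shape = process$shape, rate = rate)
}

#' Simulate a percept-report stream for an ambiguous interval
#'
#' Alternating horizontal/vertical percept events with truncated-gamma
#' dwell times, clipped at `total_s`; deterministic given the seed. An
#' optional constant report latency shifts onsets (percept-locked analyses
#' time-lock to the report, not the internal switch).
#'
#' @param process A [percept_process()].
#' @param total_s Length of the interval to fill (s).
#' @param seed Integer seed.
#' @param start_onset_s Onset of the interval within the run (s).
#' @param lag_s Constant report latency added to every onset (s).
#' @param first Condition of the first percept ("horizontal"/"vertical"),
#'   or NULL to randomize.
#' @return Percept-source events table.
#' @export
sample_percept_stream <- function(process, total_s, seed,
                                  start_onset_s = 0, lag_s = 0, first = NULL) {
  stopifnot(inherits(process, "percept_process"), total_s > 0)
  with_seed(seed, {
    n_guess <- ceiling(total_s / process$min_dwell_s) + 2L
    dwells <- sample_dwells(process, n_guess)
    cum <- cumsum(dwells)
    keep <- which(cum - dwells < total_s)
    dwells <- dwells[keep]
    # clip the last dwell at the interval end
    over <- cumsum(dwells) > total_s
    if (any(over)) {
      k <- which(over)[1L]
      dwells <- dwells[seq_len(k)]
      dwells[k] <- total_s - sum(dwells[-k])
    }
    if (is.null(first)) first <- sample(c("horizontal", "vertical"), 1L)
  })
  other <- setdiff(c("horizontal", "vertical"), first)
  conds <- rep(c(first, other), length.out = length(dwells))
  onsets <- start_onset_s + lag_s + cumsum(c(0, dwells[-length(dwells)]))
  new_events(onsets, dwells, conds, "percept")
}

#' Build an ambiguous motion-quartet run schedule with percept reports
#'
#' Same block scheme as the physical run, with each 80-s motion super-block
#' replaced by a constant ambiguous quartet; a simulated percept-report
#' stream fills each ambiguous block.
#'
#' @inheritParams build_physical_schedule
#' @param process A [percept_process()].
#' @param seed Integer seed for the percept streams.
#' @param lag_s Constant report latency (s).
#' @return List with `events` (stimulus + percept sources), `tr_s`,
#'   `n_volumes`, and `total_s`.
#' @export
build_ambiguous_schedule <- function(process = percept_process(), seed = 1,
                                     motion_block_s = 10, alternations = 4,
                                     flicker_s = 16, repetitions = 6,
                                     fixation_s = 20, fixation_both_ends = TRUE,
                                     tr_s = 2, lag_s = 0) {
  stim <- build_block_events(motion_block_s, alternations, flicker_s,
                             repetitions, fixation_s, fixation_both_ends,
                             ambiguous = TRUE)
  stim$source <- "stimulus"
  amb <- stim[stim$trial_type == "ambiguous", , drop = FALSE]
  seeds <- fan_seeds(seed, nrow(amb))
  percept <- do.call(rbind, lapply(seq_len(nrow(amb)), function(i) {
    sample_percept_stream(process, amb$duration[i], seeds[i],
                          start_onset_s = amb$onset[i], lag_s = lag_s)
  }))
  ev <- rbind(stim, percept)
  ev <- ev[order(ev$source, ev$onset), ]
  rownames(ev) <- NULL
  total <- sum(stim$duration)
  list(events = ev, tr_s = tr_s, n_volumes = as.integer(floor(total / tr_s)),
       total_s = total)
}

#' Screen a percept stream for an adequate switch rate
#'
#' Participants are retained only when perception switches at least once
#' every `window_s` seconds throughout the run, i.e. every inter-switch
#' interval (percept dwell) is at most `window_s`. The boundary is
#' inclusive: a dwell exactly equal to the window passes.
#'
#' @param events Percept-source events table.
#' @param window_s Screening window (s), default 5.
#' @return TRUE if the stream passes screening.
#' @export
screen_switch_rate <- function(events, window_s = 5) {
  ev <- events[events$source == "percept", , drop = FALSE]
  if (nrow(ev) == 0L) stop("screening undefined: no percept events", call. = FALSE)
  all(ev$duration <= window_s + 1e-12)
}

#' Mean of the truncated gamma dwell distribution
#'
#' Closed-form mean of a gamma truncated to `[a, b]` (used to document the
#' percept process; tests check the sampler against numeric integration
#' independently).
#'
#' @param process A [percept_process()].
#' @return Mean dwell time (s).
#' @export
truncated_dwell_mean <- function(process) {
  sh <- process$shape
  rate <- sh / process$mean_dwell_s
  a <- process$min_dwell_s; b <- process$max_dwell_s
  z <- stats::pgamma(b, sh, rate) - stats::pgamma(a, sh, rate)
  num <- (sh / rate) * (stats::pgamma(b, sh + 1, rate) - stats::pgamma(a, sh + 1, rate))
  num / z
}
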