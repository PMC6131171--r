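#' Trial timing configuration
#'
#' Defaults follow the task's published protocol: a 100 ms fixation cross, a
#' 150 ms primer flash, a target held until response, and an inter-trial
#' interval of 500 +/- 100 ms (uniform jitter, to minimise presentation
#' expectancy). A response timeout (absent from the original protocol) bounds
#' simulated trials.
#'
#' @param fixation_ms,primer_ms Event durations, ms.
#' @param target_timeout_ms Maximum target display time, ms.
#' @param iti_base_ms,iti_jitter_ms ITI is uniform on base +/- jitter, ms.
#' @param block_break_s Rest break between blocks, seconds.
#' @return A validated list of class `psicat_timing_config`.
#' @export
timing_config <- function(fixation_ms = 100, primer_ms = 150,
                          target_timeout_ms = 3000,
                          iti_base_ms = 500, iti_jitter_ms = 100,
                          block_break_s = 60) {
  stopifnot(fixation_ms > 0, primer_ms > 0, target_timeout_ms > 0,
            iti_base_ms > 0, block_break_s > 0,
            iti_jitter_ms >= 0, iti_jitter_ms < iti_base_ms)
  structure(list(fixation_ms = fixation_ms, primer_ms = primer_ms,
                 target_timeout_ms = target_timeout_ms,
                 iti_base_ms = iti_base_ms, iti_jitter_ms = iti_jitter_ms,
                 block_break_s = block_break_s),
            class = "psicat_timing_config")
}

#' The eight trial condition cells
#'
#' Congruency (con/inc) x target class (SCI/noSCI) x vertex count (3/4).
#' The primary conditions of interest are the four congruency x class cells;
#' vertex count is a control dimension.
#'
#' @return A tibble with columns `congruency`, `target_class`, `n_vertices`.
#' @export
condition_cells <- function() {
  tidyr::expand_grid(congruency = c("con", "inc"),
                     target_class = c("SCI", "noSCI"),
                     n_vertices = c(3L, 4L))
}

#' Counterbalanced response-hand assignment
#'
#' Alternates the SCI response hand by participant parity: even indices map
#' SCI to the right hand, odd indices to the left.
#'
#' @param participant_index Non-negative integer.
#' @return Named character vector with elements `SCI` and `noSCI`.
#' @export
assign_response_hands <- function(participant_index) {
  stopifnot(participant_index >= 0)
  if (participant_index %% 2 == 0) c(SCI = "right", noSCI = "left")
  else c(SCI = "left", noSCI = "right")
}

schedule_trials <- function(conds, timing, seed_base, block_index,
                            block_start_ms, nominal_rt_ms) {
  n <- nrow(conds)
  iti <- stats::runif(n, timing$iti_base_ms - timing$iti_jitter_ms,
                      timing$iti_base_ms + timing$iti_jitter_ms)
  trial_dur <- timing$fixation_ms + timing$primer_ms + nominal_rt_ms + iti
  fixation_onset <- block_start_ms + cumsum(c(0, trial_dur[-n]))
  tibble::tibble(
    block = block_index,
    congruency = conds$congruency,
    target_class = conds$target_class,
    n_vertices = conds$n_vertices,
    stimulus_seed = seed_base + seq_len(n),
    iti_ms = iti,
    fixation_onset_ms = fixation_onset,
    primer_onset_ms = fixation_onset + timing$fixation_ms,
    target_onset_ms = fixation_onset + timing$fixation_ms + timing$primer_ms
  )
}

#' Build a full test schedule
#'
#' Five blocks of 110 trials by default. Each trial's condition is drawn
#' independently and uniformly from the eight cells (uniform random
#' distribution, not exact stratification: 550 is not divisible by 8). Each
#' trial carries a fresh stimulus seed so that every target/primer pair is a
#' newly generated irregular polygon. Event onsets are provisional, computed
#' with a nominal response time; [realize_timeline()] replaces them once
#' responses exist. The whole schedule is a pure function of `(configs, seed)`.
#'
#' @param timing A [timing_config()].
#' @param geometry A [geometry_config()] (recorded for stimulus realization).
#' @param seed Integer seed.
#' @param n_blocks,trials_per_block Schedule shape.
#' @param participant_index Used for response-hand counterbalancing.
#' @param nominal_rt_ms Placeholder response time for provisional onsets.
#' @return A list of class `psicat_schedule` with `trials` (tibble, one row
#'   per trial), `response_hands`, `timing`, `geometry`, `is_practice`, `seed`.
#' @export
build_schedule <- function(timing = timing_config(),
                           geometry = geometry_config(), seed = 1,
                           n_blocks = 5, trials_per_block = 110,
                           participant_index = 0, nominal_rt_ms = 750) {
  withr::local_seed(seed)
  cells <- condition_cells()
  blocks <- vector("list", n_blocks)
  clock <- 0
  for (b in seq_len(n_blocks)) {
    draw <- sample.int(nrow(cells), trials_per_block, replace = TRUE)
    blocks[[b]] <- schedule_trials(cells[draw, ], timing,
                                   derive_seed(seed, b * 100000L), b, clock,
                                   nominal_rt_ms)
    clock <- max(blocks[[b]]$target_onset_ms) + nominal_rt_ms +
      blocks[[b]]$iti_ms[trials_per_block] +
      if (b < n_blocks) timing$block_break_s * 1000 else 0
  }
  trials <- dplyr::bind_rows(blocks)
  trials$trial_index <- seq_len(nrow(trials))
  trials <- dplyr::relocate(trials, "trial_index")
  structure(list(trials = trials,
                 response_hands = assign_response_hands(participant_index),
                 participant_index = participant_index,
                 timing = timing, geometry = geometry,
                 is_practice = FALSE, seed = seed),
            class = "psicat_schedule")
}

#' Build the practice schedule
#'
#' Twelve trials: exactly three per primary (congruency x class) condition,
#' with vertex counts alternating 3/4/3 across the three repetitions, in
#' shuffled order.
#'
#' @inheritParams build_schedule
#' @return A `psicat_schedule` with `is_practice = TRUE`.
#' @export
build_practice <- function(timing = timing_config(),
                           geometry = geometry_config(), seed = 1,
                           participant_index = 0, nominal_rt_ms = 750) {
  withr::local_seed(seed)
  primary <- tidyr::expand_grid(congruency = c("con", "inc"),
                                target_class = c("SCI", "noSCI"))
  conds <- tidyr::expand_grid(primary, rep = 1:3)
  conds$n_vertices <- c(3L, 4L, 3L)[conds$rep]
  conds <- conds[sample.int(nrow(conds)), c("congruency", "target_class",
                                            "n_vertices")]
  trials <- schedule_trials(conds, timing, derive_seed(seed, 990000L), 1L, 0,
                            nominal_rt_ms)
  trials$trial_index <- seq_len(nrow(trials))
  trials <- dplyr::relocate(trials, "trial_index")
  structure(list(trials = trials,
                 response_hands = assign_response_hands(participant_index),
                 participant_index = participant_index,
                 timing = timing, geometry = geometry,
                 is_practice = TRUE, seed = seed),
            class = "psicat_schedule")
}

#' Realize the session timeline from responses
#'
#' Replaces the schedule's provisional event onsets with onsets computed from
#' the actual per-trial response times, so that each trial occupies
#' fixation + primer + RT + ITI, with block breaks between blocks.
#'
#' @param schedule A `psicat_schedule`.
#' @param responses Tibble from [simulate_responses()] (needs `rt_ms`).
#' @return The schedule with updated onsets and a `rt_ms` column.
#' @export
realize_timeline <- function(schedule, responses) {
  tr <- schedule$trials
  if (nrow(responses) != nrow(tr)) {
    stop("responses do not cover the schedule (", nrow(responses), " vs ",
         nrow(tr), " trials)", call. = FALSE)
  }
  timing <- schedule$timing
  rt <- responses$rt_ms
  dur <- timing$fixation_ms + timing$primer_ms + rt + tr$iti_ms +
    c(ifelse(diff(tr$block) > 0, timing$block_break_s * 1000, 0), 0)
  tr$fixation_onset_ms <- cumsum(c(0, dur[-length(dur)]))
  tr$primer_onset_ms <- tr$fixation_onset_ms + timing$fixation_ms
  tr$target_onset_ms <- tr$primer_onset_ms + timing$primer_ms
  tr$rt_ms <- rt
  schedule$trials <- tr
  schedule
}

#' Export a schedule as an events table
#'
#' One row per event (fixation, primer, target, response, break) in a
#' BIDS-events-style dialect: `onset` and `duration` in seconds plus trial
#' metadata columns. Round-trips losslessly through [read_events()].
#'
#' @param schedule A `psicat_schedule`, ideally after [realize_timeline()].
#' @param responses Optional responses tibble ([simulate_responses()]); adds
#'   response events and `response`/`rt_ms`/`correct` fields.
#' @return A tibble of events ordered by onset.
#' @export
export_events <- function(schedule, responses = NULL) {
  tr <- schedule$trials
  timing <- schedule$timing
  rt <- if (!is.null(responses)) responses$rt_ms else rep(NA_real_, nrow(tr))
  meta <- tr[, c("trial_index", "block", "congruency", "target_class",
                 "n_vertices")]
  ev <- function(type, onset_ms, duration_ms, extra = NULL) {
    out <- tibble::tibble(onset = onset_ms / 1000,
                          duration = duration_ms / 1000,
                          event_type = type, meta)
    out$response <- NA_character_
    out$rt_ms <- NA_real_
    out$correct <- NA
    if (!is.null(extra)) out[names(extra)] <- extra
    out
  }
  events <- dplyr::bind_rows(
    ev("fixation", tr$fixation_onset_ms, timing$fixation_ms),
    ev("primer", tr$primer_onset_ms, timing$primer_ms),
    ev("target", tr$target_onset_ms,
       ifelse(is.na(rt), timing$target_timeout_ms, rt)),
    if (!is.null(responses)) {
      ev("response", tr$target_onset_ms + rt, 0,
         extra = list(response = responses$button, rt_ms = rt,
                      correct = responses$correct))
    }
  )
  breaks <- which(diff(tr$block) > 0)
  if (length(breaks) > 0 && !schedule$is_practice) {
    onset <- tr$target_onset_ms[breaks] +
      (if (!is.null(responses)) rt[breaks] else timing$target_timeout_ms) +
      tr$iti_ms[breaks]
    events <- dplyr::bind_rows(
      events,
      tibble::tibble(onset = onset / 1000,
                     duration = timing$block_break_s,
                     event_type = "break",
                     trial_index = NA_integer_,
                     block = tr$block[breaks],
                     congruency = NA_character_,
                     target_class = NA_character_,
                     n_vertices = NA_integer_,
                     response = NA_character_, rt_ms = NA_real_,
                     correct = NA))
  }
  dplyr::arrange(events, .data$onset, .data$event_type)
}
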