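# small in-code fixtures shared across test files

fast_schedule <- function(seed = 1, n_blocks = 1, trials_per_block = 40,
                          participant_index = 0) {
  build_schedule(seed = seed, n_blocks = n_blocks,
                 trials_per_block = trials_per_block,
                 participant_index = participant_index)
}

# epochs built directly from a channels x samples generator function f(t_ms)
# replicated over epochs, bypassing the simulator
synthetic_epochs <- function(n_epochs, channels, fgen, fs = 512,
                             conditions = NULL) {
  times <- psicat:::epoch_times_ms(fs)
  dat <- array(0, dim = c(n_epochs, length(channels), length(times)))
  for (e in seq_len(n_epochs)) {
    w <- fgen(times, e)
    if (is.null(dim(w))) w <- matrix(w, length(channels), length(times),
                                     byrow = TRUE)
    dat[e, , ] <- w
  }
  info <- tibble::tibble(trial_index = seq_len(n_epochs),
                         block = 1L,
                         congruency = rep_len(c("con", "inc"), n_epochs),
                         target_class = rep_len(c("SCI", "SCI", "noSCI",
                                                  "noSCI"), n_epochs),
                         n_vertices = 3L,
                         onset = seq_len(n_epochs) * 1.5,
                         rt_ms = 500, correct = TRUE)
  if (!is.null(conditions)) info[names(conditions)] <- conditions
  structure(list(data = dat, times_ms = times, channels = channels,
                 info = info, baseline_mode = "none", fs = fs),
            class = "psicat_epochs")
}

make_subsets <- function(n, k = floor(n / 2)) {
  structure(list(early = seq_len(k), late = (n - k + 1):n, n_each = k),
            class = "psicat_subsets")
}

# tiny session for IO tests: a few seconds of two named channels
tiny_session <- function(seed = 1) {
  sched <- fast_schedule(seed = seed, trials_per_block = 10)
  bm <- default_behavior_model()
  resp <- simulate_responses(sched, bm, seed = seed)
  nm <- default_neural_model()
  simulate_recording(sched, resp, nm, seed = seed)
}
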