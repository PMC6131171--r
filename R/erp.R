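## Filtering ------------------------------------------------------------------

# apply an odd-length symmetric FIR centred (exactly zero-phase), zero-padded;
# FFT convolution for long inputs, direct convolution for short ones
apply_fir_centered <- function(x, h, pad = c("zero", "reflect")) {
  stopifnot(length(h) %% 2 == 1)
  pad <- match.arg(pad)
  half <- (length(h) - 1) / 2
  if (pad == "reflect") {
    # mirror-extend so short segments keep their level at the edges
    n0 <- length(x)
    ext <- min(half, n0 - 1)
    x <- c(rev(x[2:(ext + 1)]), x, rev(x[(n0 - ext):(n0 - 1)]))
    y <- apply_fir_centered(x, h, pad = "zero")
    return(y[(ext + 1):(ext + n0)])
  }
  n <- length(x)
  if (as.numeric(n) * length(h) > 2e7) {
    np <- stats::nextn(n + length(h) - 1)
    Y <- stats::fft(c(x, numeric(np - n))) *
      stats::fft(c(h, numeric(np - length(h))))
    y <- Re(stats::fft(Y, inverse = TRUE)) / np
    return(y[(half + 1):(half + n)])
  }
  y <- stats::filter(c(numeric(half), x, numeric(half)), h, sides = 2,
                     method = "convolution")
  as.numeric(y[(half + 1):(half + length(x))])
}

# least-squares linear-phase FIR high-pass (type I): minimizes the integrated
# squared error against a desired response of 0 on [0, 0.85*cutoff] and 1 on
# [cutoff, Nyquist], with a don't-care transition between. The band integrals
# of cos(j*w)cos(k*w) have closed forms, so the normal equations are exact.
fir_ls_highpass <- function(ord, w_stop, w_pass) {
  M <- ord / 2
  I_band <- function(m, a, b) ifelse(m == 0, b - a,
                                     (sin(m * b) - sin(m * a)) / m)
  j <- 0:M
  jk_minus <- outer(j, j, "-")
  jk_plus <- outer(j, j, "+")
  Q <- 0.5 * (I_band(jk_minus, 0, w_stop) + I_band(jk_plus, 0, w_stop)) +
    0.5 * (I_band(jk_minus, w_pass, pi) + I_band(jk_plus, w_pass, pi))
  bvec <- I_band(j, w_pass, pi)
  # cos(0*w) enters A(w) once, cos(k*w) terms carry weight 2 in the expansion
  scale <- ifelse(j == 0, 1, 2)
  Q <- Q * outer(scale, scale)
  bvec <- bvec * scale
  # equality-constrain A(0) = sum over scaled cosines at w=0 to exactly zero
  # (Lagrange): the filter then rejects DC perfectly, not just approximately
  cvec <- scale
  KKT <- rbind(cbind(2 * Q, cvec), c(cvec, 0))
  sol <- solve(KKT, c(2 * bvec, 0))
  a <- sol[seq_len(M + 1)]
  c(rev(a[-1]), a[1], a[-1])
}

highpass_kernel <- function(fs, cutoff = 0.5) {
  ord <- round(1.5 * fs)
  if (ord %% 2 == 1) ord <- ord + 1          # even order -> odd taps, type I
  nyq <- fs / 2
  fir_ls_highpass(ord, pi * 0.85 * cutoff / nyq, pi * cutoff / nyq)
}

#' High-pass filter a continuous recording
#'
#' Linear-phase FIR high-pass (order 1.5 x sampling rate; stopband up to 85%
#' of the cutoff, passband from the cutoff), applied centred so the net filter
#' is exactly zero-phase. Removes DC and slow drift while leaving task-band
#' activity untouched.
#'
#' @param session A `psicat_session` (or a plain numeric matrix channels x
#'   samples with attribute-free data plus `fs` given).
#' @param cutoff Cutoff frequency, Hz.
#' @param fs Sampling rate, needed only for matrix input.
#' @return Same type as the input, filtered.
#' @export
highpass <- function(session, cutoff = 0.5, fs = NULL) {
  if (inherits(session, "psicat_session")) {
    h <- highpass_kernel(session$fs, cutoff)
    if (ncol(session$eeg) < 3 * length(h)) {
      stop("recording shorter than 3x the filter length", call. = FALSE)
    }
    session$eeg <- t(apply(session$eeg, 1, apply_fir_centered, h = h))
    dimnames(session$eeg) <- list(session$channels, NULL)
    return(session)
  }
  stopifnot(!is.null(fs))
  h <- highpass_kernel(fs, cutoff)
  if (NCOL(session) < 3 * length(h)) {
    stop("recording shorter than 3x the filter length", call. = FALSE)
  }
  if (is.matrix(session)) t(apply(session, 1, apply_fir_centered, h = h))
  else apply_fir_centered(session, h)
}

## Epoching -------------------------------------------------------------------

# epoch time axis: 384 samples at 512 Hz spanning -250 ms .. +498 ms, with
# target onset exactly at sample 129 (0 ms)
epoch_times_ms <- function(fs = 512) {
  n <- round(0.75 * fs)
  (seq_len(n) - 1 - round(0.25 * fs)) / fs * 1000
}

#' Extract target-locked epochs from a session
#'
#' Cuts 750 ms epochs (100 ms pre-trial baseline, 150 ms primer, 500 ms
#' post-target: -250 to +500 ms around target onset), time-locked to target
#' events. Error trials are excluded when `hits_only` (the default, matching
#' the ERP analysis); epochs that would run past the recording edge are
#' dropped with a message.
#'
#' @param session A `psicat_session`.
#' @param hits_only Keep correct trials only.
#' @return A list of class `psicat_epochs`: `data` (epochs x channels x
#'   samples array, microvolts), `times_ms`, `channels`, `info` (one row per
#'   epoch: trial index, condition, correctness, rt), `baseline_mode`
#'   (`"none"`), `fs`.
#' @export
epoch_recording <- function(session, hits_only = TRUE) {
  fs <- session$fs
  times <- epoch_times_ms(fs)
  n_samp <- length(times)
  pre <- round(0.25 * fs)
  targets <- session$events[session$events$event_type == "target", ]
  info <- dplyr::left_join(
    targets[, c("trial_index", "block", "congruency", "target_class",
                "n_vertices", "onset")],
    session$responses[, c("trial_index", "rt_ms", "correct")],
    by = "trial_index")
  if (hits_only) info <- info[info$correct, ]
  onset_idx <- round(info$onset * fs) + 1
  ok <- onset_idx - pre >= 1 & onset_idx - pre + n_samp - 1 <= ncol(session$eeg)
  if (any(!ok)) {
    message(sum(!ok), " epoch(s) dropped at recording edge")
    info <- info[ok, ]
    onset_idx <- onset_idx[ok]
  }
  data <- array(0, dim = c(nrow(info), length(session$channels), n_samp))
  for (e in seq_len(nrow(info))) {
    i0 <- onset_idx[e] - pre
    data[e, , ] <- session$eeg[, i0:(i0 + n_samp - 1)]
  }
  structure(list(data = data, times_ms = times, channels = session$channels,
                 info = tibble::as_tibble(info), baseline_mode = "none",
                 fs = fs),
            class = "psicat_epochs")
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per epoch and channel, the mean voltage over the baseline window
#' of the requested mode: `"trial"` uses -250..-150 ms (the 100 ms preceding
#' the whole trial; used for congruency questions and the primer N1) and
#' `"target"` uses -100..0 ms (the period immediately before target onset;
#' used for target-locked gestalt questions, to control primer carry-over
#' trial by trial).
#'
#' @param epochs A `psicat_epochs`.
#' @param mode `"trial"` or `"target"`.
#' @return The corrected `psicat_epochs`, with `baseline_mode` recorded.
#' @export
baseline_correct <- function(epochs, mode = c("trial", "target")) {
  mode <- match.arg(mode)
  win <- baseline_window_ms(mode)
  idx <- which(epochs$times_ms >= win[1] & epochs$times_ms <= win[2])
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)   # recycles over 3rd dim
  epochs$baseline_mode <- mode
  epochs
}

#' 20 Hz low-pass for visualisation and windowed testing
#'
#' Zero-phase FIR low-pass applied per epoch and channel.
#'
#' @param epochs A `psicat_epochs`.
#' @param cutoff Cutoff, Hz.
#' @param order Filter order (even).
#' @return Filtered `psicat_epochs`.
#' @export
lowpass20 <- function(epochs, cutoff = 20, order = 128) {
  h <- signal::fir1(order, cutoff / (epochs$fs / 2), type = "low")
  d <- epochs$data
  for (e in seq_len(dim(d)[1])) {
    for (ch in seq_len(dim(d)[2])) {
      d[e, ch, ] <- apply_fir_centered(d[e, ch, ], h, pad = "reflect")
    }
  }
  epochs$data <- d
  epochs
}

#' Reject epochs exceeding an absolute amplitude threshold
#'
#' Simple artifact hook: drops any epoch whose absolute amplitude exceeds the
#' threshold on any channel.
#'
#' @param epochs A `psicat_epochs`.
#' @param threshold_uv Rejection threshold, microvolts.
#' @return The pruned `psicat_epochs`.
#' @export
reject_epochs <- function(epochs, threshold_uv = 100) {
  keep <- apply(abs(epochs$data), 1, max) <= threshold_uv
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$info <- epochs$info[keep, ]
  epochs
}

## Windowed amplitude ---------------------------------------------------------

#' Windowed mean ROI amplitude per condition
#'
#' Mean amplitude over the ROI channels and a component window (closed
#' interval, nearest-sample rounding), then averaged over epochs within each
#' grouping cell. Mean-across-window is used instead of peak picking.
#'
#' @param epochs A baseline-corrected `psicat_epochs`.
#' @param roi ROI name (see [roi_definitions()]).
#' @param window Component name from [component_windows()], or a numeric
#'   `c(lo, hi)` in ms.
#' @param by Character vector of grouping columns in `epochs$info`.
#' @return Tibble: grouping columns, `mean_uv`, `n_epochs`.
#' @export
roi_window_amplitude <- function(epochs, roi, window,
                                 by = c("congruency", "target_class")) {
  ch_idx <- match(roi_channels(roi), epochs$channels)
  if (anyNA(ch_idx)) stop("epochs lack ROI channels", call. = FALSE)
  if (is.character(window)) {
    w <- component_windows()
    w <- w[w$component == window, ]
    if (nrow(w) == 0) stop("unknown component window '", window, "'",
                           call. = FALSE)
    window <- c(w$center_ms - w$half_width_ms, w$center_ms + w$half_width_ms)
  }
  t_idx <- which(epochs$times_ms >= window[1] & epochs$times_ms <= window[2])
  per_epoch <- apply(epochs$data[, ch_idx, t_idx, drop = FALSE], 1, mean)
  epochs$info |>
    dplyr::mutate(.amp = per_epoch) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(mean_uv = mean(.data$.amp),
                     n_epochs = dplyr::n(), .groups = "drop")
}

## Tests and effect sizes -----------------------------------------------------

#' One-tailed paired t test
#'
#' Paired-sample t test with df = n - 1, one-sided in the stated direction
#' (`"greater"` tests a > b). Effects in the wrong direction give p > 0.5.
#'
#' @param a,b Paired numeric vectors.
#' @param direction `"greater"` or `"less"` (a vs b).
#' @return One-row tibble: `mean_diff`, `t`, `df`, `p`, `degenerate`.
#' @export
paired_t_one_tailed <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  d <- a - b
  if (length(d) < 2 || stats::sd(d) == 0) {
    return(tibble::tibble(mean_diff = mean(d), t = NA_real_,
                          df = length(d) - 1, p = NA_real_,
                          degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE, alternative = direction)
  tibble::tibble(mean_diff = mean(d), t = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 degenerate = FALSE)
}

#' Cohen's d from a paired t statistic
#'
#' `d = t * sqrt(2 / n)`, the conversion consistent with the published
#' condition-contrast effect sizes (t = 6.68, n = 17 gives d = 2.29).
#'
#' @param t t statistic.
#' @param n Number of participants.
#' @return Cohen's d.
#' @export
es_from_t <- function(t, n) {
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  t * sqrt(2 / n)
}

## Battery --------------------------------------------------------------------

erp_hypotheses <- function() {
  tibble::tribble(
    ~hypothesis, ~stratum, ~component, ~roi,       ~contrast,    ~direction,
    "H3P3a",  NA,    "P3a", "vertex",    "congruency", "greater",
    "H3P3b",  NA,    "P3b", "parietal",  "congruency", "less",
    "H4pN1",  NA,    "pN1", "occipital", "sci",        "less",
    "H4tN1",  "con", "tN1", "occipital", "sci",        "less",
    "H4tN1",  "inc", "tN1", "occipital", "sci",        "less",
    "H4tP3a", "con", "P3a", "vertex",    "sci",        "greater",
    "H4tP3a", "inc", "P3a", "vertex",    "sci",        "greater"
  )
}

#' Per-participant windowed ERP measures
#'
#' Runs the full measurement chain on one participant's session: epoch (hits
#' only), baseline-correct under both modes, 20 Hz low-pass, and compute the
#' windowed ROI mean amplitudes every hypothesis needs. Congruency questions
#' (P3a, P3b) and the primer N1 use the trial baseline; target-locked gestalt
#' questions (target N1, target P3a) use the target baseline.
#'
#' @param session A `psicat_session`, already high-pass filtered if desired.
#' @param reject_uv Optional artifact threshold (microvolts); `NULL` disables.
#' @return Tibble: `participant_id`, `measure`, `congruency`, `target_class`,
#'   `mean_uv`, `n_epochs`.
#' @export
erp_measures <- function(session, reject_uv = NULL) {
  ep <- epoch_recording(session, hits_only = TRUE)
  if (!is.null(reject_uv)) ep <- reject_epochs(ep, reject_uv)
  measures <- list(
    list(name = "P3a_trial", mode = "trial", roi = "vertex", win = "P3a"),
    list(name = "P3b_trial", mode = "trial", roi = "parietal", win = "P3b"),
    list(name = "pN1_trial", mode = "trial", roi = "occipital", win = "pN1"),
    list(name = "tN1_target", mode = "target", roi = "occipital", win = "tN1"),
    list(name = "P3a_target", mode = "target", roi = "vertex", win = "P3a")
  )
  by_mode <- list(trial = lowpass20(baseline_correct(ep, "trial")),
                  target = lowpass20(baseline_correct(ep, "target")))
  purrr::map_dfr(measures, function(m) {
    roi_window_amplitude(by_mode[[m$mode]], m$roi, m$win) |>
      dplyr::mutate(measure = m$name, .before = 1)
  }) |>
    dplyr::mutate(participant_id = session$participant_id, .before = 1)
}

measure_for_hypothesis <- function(hyp) {
  c(H3P3a = "P3a_trial", H3P3b = "P3b_trial", H4pN1 = "pN1_trial",
    H4tN1 = "tN1_target", H4tP3a = "P3a_target")[[hyp]]
}

#' ERP hypothesis battery across participants
#'
#' One-tailed paired t tests of the windowed amplitudes for the seven
#' condition contrasts (P3a and P3b congruency contrasts; primer N1, target
#' N1, and target P3a gestalt contrasts, the target-locked ones within each
#' congruency stratum), Holm-adjusted as one family, with Cohen's d from t.
#' Differences are reported as congruent minus incongruent for congruency
#' contrasts and SCI minus no-SCI for gestalt contrasts.
#'
#' @param measures Row-bound output of [erp_measures()] over participants.
#' @return Tibble with one row per hypothesis: `hypothesis`, `stratum`,
#'   `diff_uv`, `t`, `df`, `p`, `adj_p`, `es`, `significant`.
#' @export
erp_test_battery <- function(measures) {
  res <- purrr::pmap_dfr(erp_hypotheses(), function(hypothesis, stratum,
                                                    component, roi, contrast,
                                                    direction) {
    m <- measures[measures$measure == measure_for_hypothesis(hypothesis), ]
    if (contrast == "congruency") {
      cell <- m |>
        dplyr::group_by(.data$participant_id, .data$congruency) |>
        dplyr::summarise(mean_uv = stats::weighted.mean(.data$mean_uv,
                                                        .data$n_epochs),
                         .groups = "drop") |>
        tidyr::pivot_wider(names_from = "congruency",
                           values_from = "mean_uv")
      a <- cell$con; b <- cell$inc
    } else {
      if (!is.na(stratum)) m <- m[m$congruency == stratum, ]
      cell <- m |>
        dplyr::group_by(.data$participant_id, .data$target_class) |>
        dplyr::summarise(mean_uv = stats::weighted.mean(.data$mean_uv,
                                                        .data$n_epochs),
                         .groups = "drop") |>
        tidyr::pivot_wider(names_from = "target_class",
                           values_from = "mean_uv")
      a <- cell$SCI; b <- cell$noSCI
    }
    tt <- paired_t_one_tailed(a, b, direction)
    tibble::tibble(hypothesis, stratum, roi, component,
                   n = sum(stats::complete.cases(a, b)),
                   diff_uv = tt$mean_diff, t = tt$t, df = tt$df, p = tt$p)
  })
  res$adj_p <- holm_bonferroni(res$p)
  res$es <- es_from_t(res$t, res$n)
  res$significant <- !is.na(res$adj_p) & res$adj_p <= 0.05
  res
}
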