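#' Early/late epoch subsets
#'
#' First and last `fraction` of epochs by trial order (floor of the count each
#' side), disjoint by construction. At least 8 epochs per subset are required.
#'
#' @param epochs A `psicat_epochs`.
#' @param fraction Subset fraction (default 0.10, emulating first/last-10%
#'   sustained-attention comparisons).
#' @return List of class `psicat_subsets`: integer vectors `early`, `late`,
#'   and `n_each`.
#' @export
subset_epochs <- function(epochs, fraction = 0.10) {
  ord <- order(epochs$info$trial_index)
  n <- length(ord)
  k <- floor(fraction * n)
  if (k < 8) stop("subsets too small (", k, " epochs); need >= 8",
                  call. = FALSE)
  structure(list(early = ord[seq_len(k)], late = ord[(n - k + 1):n],
                 n_each = k),
            class = "psicat_subsets")
}

## Welch PSD ------------------------------------------------------------------

# Hann-windowed periodogram of one epoch (power per frequency bin)
periodogram_hann <- function(x) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  xw <- (x - mean(x)) * w
  P <- Mod(stats::fft(xw))^2 / sum(w^2)
  P[seq_len(n %/% 2 + 1)]
}

#' Welch power spectrum of epoch subsets at an ROI
#'
#' FFT power estimate: one Hann-windowed modified periodogram per epoch and
#' ROI channel, averaged within each subset. Frequencies limited to 1--30 Hz.
#'
#' @param epochs A `psicat_epochs`.
#' @param subsets A [subset_epochs()] result.
#' @param roi ROI name (default the fronto-medial ROI, C19--C21).
#' @return List of class `psicat_spectral` with `kind = "psd"`, `freq_hz`,
#'   `early`/`late` (mean power), `per_epoch` (bins x epochs matrix with a
#'   `labels` attribute) for permutation testing.
#' @export
psd_subsets <- function(epochs, subsets, roi = "frontomedial") {
  ch_idx <- match(roi_channels(roi), epochs$channels)
  if (anyNA(ch_idx)) stop("epochs lack ROI channels", call. = FALSE)
  n <- length(epochs$times_ms)
  freq <- (seq_len(n %/% 2 + 1) - 1) * epochs$fs / n
  keep <- freq >= 1 & freq <= 30
  idx <- c(subsets$early, subsets$late)
  if (length(idx) < 16) stop("subset too small for spectral estimation",
                             call. = FALSE)
  per_epoch <- vapply(idx, function(e) {
    rowMeans(vapply(ch_idx, function(ch) {
      periodogram_hann(epochs$data[e, ch, ])[keep]
    }, numeric(sum(keep))))
  }, numeric(sum(keep)))
  labels <- rep(c("early", "late"), each = subsets$n_each)
  attr(per_epoch, "labels") <- labels
  structure(list(kind = "psd", freq_hz = freq[keep], time_ms = NULL,
                 early = rowMeans(per_epoch[, labels == "early"]),
                 late = rowMeans(per_epoch[, labels == "late"]),
                 per_epoch = per_epoch),
            class = "psicat_spectral")
}

## Wavelet ERSP / ITC ---------------------------------------------------------

# complex Morlet-style wavelet coefficients for one time series, one frequency
# (n_cycles fixed-cycle wavelet, truncated at 2.5 sd). Near the epoch edges
# the data is zero-padded and the coefficient renormalized by the kernel mass
# that overlaps real samples, so coherent amplitude stays unbiased at edges.
wavelet_kernel <- function(fs, freq, n_cycles = 3) {
  sd_t <- n_cycles / (2 * pi * freq)
  half <- ceiling(2.5 * sd_t * fs)
  tt <- (-half:half) / fs
  kern <- exp(2i * pi * freq * tt) * exp(-tt^2 / (2 * sd_t^2))
  kern / sum(abs(kern))
}

wavelet_coef <- function(x, fs, freq, n_cycles = 3) {
  kern <- wavelet_kernel(fs, freq, n_cycles)
  half <- (length(kern) - 1) / 2
  xp <- c(numeric(half), x, numeric(half))
  out <- stats::convolve(xp, Conj(rev(kern)), type = "filter")[seq_along(x)]
  mass <- stats::convolve(c(numeric(half), rep(1, length(x)), numeric(half)),
                          abs(rev(kern)), type = "filter")[seq_along(x)]
  out / mass
}

# coefficients for a set of epochs at one channel: list over frequencies of
# (time x epoch) complex matrices
wavelet_decompose <- function(epochs, epoch_idx, channel, freqs, n_cycles = 3) {
  ch <- match(channel, epochs$channels)
  if (is.na(ch)) stop("channel ", channel, " not in epochs", call. = FALSE)
  epoch_len_s <- length(epochs$times_ms) / epochs$fs
  resolvable <- 2 * 2.5 * n_cycles / (2 * pi * freqs) <= epoch_len_s
  if (any(!resolvable)) {
    message("excluding unresolvable frequencies: ",
            paste(freqs[!resolvable], collapse = ", "), " Hz")
    freqs <- freqs[resolvable]
  }
  coefs <- lapply(freqs, function(f) {
    vapply(epoch_idx, function(e) {
      wavelet_coef(epochs$data[e, ch, ], epochs$fs, f, n_cycles)
    }, complex(length(epochs$times_ms)))
  })
  list(freqs = freqs, coefs = coefs)
}

#' Event-related spectral perturbation of epoch subsets
#'
#' Time-frequency power from a 3-cycle complex wavelet transform at one
#' channel, expressed in dB relative to the mean pre-trial baseline power
#' (-250..-150 ms) pooled over BOTH subsets, so that a session-long drift in
#' absolute power shows up as opposite-signed deviations rather than being
#' normalised away. Times limited to 0--300 ms after target onset; the
#' frequency grid is 4--30 Hz (the 750 ms epoch cannot support lower
#' frequencies).
#'
#' @param epochs A `psicat_epochs`.
#' @param subsets A [subset_epochs()] result.
#' @param channel Channel label (default `"C20"`, the fronto-medial midline).
#' @param freqs Frequency grid, Hz.
#' @param n_cycles Wavelet cycles.
#' @param time_step_ms Time grid spacing.
#' @return List of class `psicat_spectral`, `kind = "ersp"`: `freq_hz`,
#'   `time_ms`, `early`/`late` (dB matrices, freq x time), `per_epoch`
#'   (baseline-normalised linear power, (freq*time) x epochs, for permutation
#'   testing), plus the wavelet decomposition reused by [itc_subsets()].
#' @export
ersp_subsets <- function(epochs, subsets, channel = "C20", freqs = 4:30,
                         n_cycles = 3, time_step_ms = 20) {
  idx <- c(subsets$early, subsets$late)
  labels <- rep(c("early", "late"), each = subsets$n_each)
  dec <- wavelet_decompose(epochs, idx, channel, freqs, n_cycles)
  t_grid <- seq(0, 300, by = time_step_ms)
  t_idx <- vapply(t_grid, function(t) which.min(abs(epochs$times_ms - t)),
                  integer(1))
  bl_idx <- which(epochs$times_ms >= -250 & epochs$times_ms <= -150)
  nf <- length(dec$freqs); nt <- length(t_grid); ne <- length(idx)
  per_epoch <- matrix(0, nf * nt, ne)
  early_m <- matrix(0, nf, nt, dimnames = list(dec$freqs, t_grid))
  late_m <- early_m
  for (fi in seq_len(nf)) {
    P <- Mod(dec$coefs[[fi]])^2                    # time x epoch
    B <- mean(P[bl_idx, ])                         # pooled-subset baseline
    rel <- P[t_idx, , drop = FALSE] / B
    per_epoch[(fi - 1) * nt + seq_len(nt), ] <- rel
    early_m[fi, ] <- 10 * log10(rowMeans(rel[, labels == "early",
                                             drop = FALSE]))
    late_m[fi, ] <- 10 * log10(rowMeans(rel[, labels == "late",
                                            drop = FALSE]))
  }
  attr(per_epoch, "labels") <- labels
  structure(list(kind = "ersp", freq_hz = dec$freqs, time_ms = t_grid,
                 early = early_m, late = late_m, per_epoch = per_epoch,
                 decomposition = dec, t_idx = t_idx, channel = channel),
            class = "psicat_spectral")
}

#' Inter-trial coherence of epoch subsets
#'
#' Phase-locking across epochs: the magnitude of the mean unit phasor of the
#' wavelet coefficients, in [0, 1], computed from the same decomposition as
#' the ERSP when one is supplied.
#'
#' @inheritParams ersp_subsets
#' @param ersp Optional [ersp_subsets()] result to reuse its coefficients.
#' @return List of class `psicat_spectral`, `kind = "itc"`: `freq_hz`,
#'   `time_ms`, `early`/`late` ITC matrices, and `per_epoch` unit-phasor
#'   components for permutation testing (complex, (freq*time) x epochs).
#' @export
itc_subsets <- function(epochs, subsets, channel = "C20", freqs = 4:30,
                        n_cycles = 3, time_step_ms = 20, ersp = NULL) {
  if (is.null(ersp)) {
    ersp <- ersp_subsets(epochs, subsets, channel, freqs, n_cycles,
                         time_step_ms)
  }
  dec <- ersp$decomposition
  t_idx <- ersp$t_idx
  labels <- attr(ersp$per_epoch, "labels")
  nf <- length(dec$freqs); nt <- length(t_idx); ne <- length(labels)
  phasors <- matrix(0i, nf * nt, ne)
  for (fi in seq_len(nf)) {
    W <- dec$coefs[[fi]][t_idx, , drop = FALSE]
    m <- Mod(W)
    m[m == 0] <- NA                                # degenerate bins excluded
    phasors[(fi - 1) * nt + seq_len(nt), ] <- W / m
  }
  itc_of <- function(sel) {
    v <- Mod(rowMeans(phasors[, sel, drop = FALSE], na.rm = TRUE))
    matrix(v, nf, nt, byrow = TRUE,
           dimnames = list(dec$freqs, ersp$time_ms))
  }
  attr(phasors, "labels") <- labels
  structure(list(kind = "itc", freq_hz = dec$freqs, time_ms = ersp$time_ms,
                 early = itc_of(labels == "early"),
                 late = itc_of(labels == "late"),
                 per_epoch = phasors, channel = ersp$channel),
            class = "psicat_spectral")
}

## Permutation testing --------------------------------------------------------

#' Label-shuffle permutation test per bin
#'
#' Two-tailed unpaired test of the observed early-minus-late difference of
#' per-bin statistics against a null built by shuffling the subset labels
#' jointly across bins. Real-valued rows compare subset means; complex rows
#' (unit phasors) compare resultant lengths, giving the ITC difference test.
#' Deterministic per seed.
#'
#' @param per_epoch Bins x epochs matrix (real or complex) with a `labels`
#'   attribute, as produced by the spectral estimators; or any such matrix
#'   plus an explicit `labels` argument.
#' @param labels Character vector, `"early"`/`"late"` per epoch.
#' @param n_perm Number of permutations (warns below 100).
#' @param alpha Significance level for the mask.
#' @param seed Integer seed.
#' @param log_transform Compare means on the dB scale (used for ERSP/PSD).
#' @return Tibble: `bin`, `observed`, `p`, `significant`.
#' @export
permutation_test <- function(per_epoch, labels = attr(per_epoch, "labels"),
                             n_perm = 500, alpha = 0.05, seed = 1,
                             log_transform = FALSE) {
  if (is.null(labels)) stop("labels required", call. = FALSE)
  if (length(unique(labels)) < 2) stop("labels are constant", call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100 gives a coarse null", call. = FALSE)
  withr::local_seed(seed)
  ne <- ncol(per_epoch)
  stat <- function(sel) {
    if (is.complex(per_epoch)) {
      Mod(rowMeans(per_epoch[, sel, drop = FALSE], na.rm = TRUE))
    } else if (log_transform) {
      10 * log10(rowMeans(per_epoch[, sel, drop = FALSE]))
    } else {
      rowMeans(per_epoch[, sel, drop = FALSE])
    }
  }
  diff_of <- function(lab) stat(lab == "early") - stat(lab == "late")
  obs <- diff_of(labels)
  exceed <- integer(length(obs))
  for (k in seq_len(n_perm)) {
    perm <- sample(labels)
    exceed <- exceed + (abs(diff_of(perm)) >= abs(obs))
  }
  p <- (exceed + 1) / (n_perm + 1)
  tibble::tibble(bin = seq_along(obs), observed = obs, p = p,
                 significant = p <= alpha)
}

#' Ten-repeat stability of a permutation mask
#'
#' Permutation masks are stochastic; repeating the test with independent seeds
#' and reporting the per-bin fraction of significant repeats shows which bins
#' are characteristic of a repeatable pattern.
#'
#' @param analysis A function `f(seed)` returning a logical significance mask
#'   (the `significant` column of [permutation_test()]).
#' @param repeats Number of repeats.
#' @param seed Base seed; repeat k uses a seed derived from it.
#' @return Numeric vector: per-bin fraction of repeats flagged significant.
#' @export
stability <- function(analysis, repeats = 10, seed = 1) {
  masks <- vapply(seq_len(repeats),
                  function(k) analysis(derive_seed(seed, k)),
                  logical(length(analysis(derive_seed(seed, 1)))))
  rowMeans(masks)
}

#' Early-versus-late spectral comparison at the fronto-medial ROI
#'
#' The full oscillatory analysis: Welch power spectrum at the fronto-medial
#' ROI, ERSP and ITC at C20, each compared between the first and last 10% of
#' epochs with label-shuffle permutation testing (alpha 0.01 for PSD and ITC,
#' 0.05 for ERSP, mirroring the reporting thresholds).
#'
#' @param epochs A `psicat_epochs` (all trials, hits and errors, unless the
#'   caller pre-filters).
#' @param fraction Subset fraction.
#' @param n_perm Permutations per test.
#' @param seed Integer seed.
#' @param subsets Optional pre-built `psicat_subsets` (e.g. pooled across
#'   participants); when given, `fraction` is ignored.
#' @return List of class `psicat_spectral_report`: elements `psd`, `ersp`,
#'   `itc` (each a `psicat_spectral` with a `test` tibble attached), plus
#'   `provenance`.
#' @export
analyze_spectral <- function(epochs, fraction = 0.10, n_perm = 500, seed = 1,
                             subsets = NULL) {
  subs <- subsets %||% subset_epochs(epochs, fraction)
  psd <- psd_subsets(epochs, subs)
  psd$test <- permutation_test(psd$per_epoch, n_perm = n_perm, alpha = 0.01,
                               seed = derive_seed(seed, 11),
                               log_transform = TRUE)
  ersp <- ersp_subsets(epochs, subs)
  ersp$test <- permutation_test(ersp$per_epoch, n_perm = n_perm, alpha = 0.05,
                                seed = derive_seed(seed, 12),
                                log_transform = TRUE)
  itc <- itc_subsets(epochs, subs, ersp = ersp)
  itc$test <- permutation_test(itc$per_epoch, n_perm = n_perm, alpha = 0.01,
                               seed = derive_seed(seed, 13))
  ersp$decomposition <- NULL                       # drop bulky coefficients
  structure(list(psd = psd, ersp = ersp, itc = itc,
                 provenance = list(fraction = fraction, n_perm = n_perm,
                                   seed = seed, n_each = subs$n_each)),
            class = "psicat_spectral_report")
}

#' Theta-band summary of a spectral report
#'
#' Convenience check of the sustained-attention signature: mean theta-band
#' (4--8 Hz) PSD early vs late with its permutation significance, and the
#' late-minus-early mean theta ITC.
#'
#' @param report An [analyze_spectral()] result.
#' @return One-row tibble: `psd_theta_early`, `psd_theta_late`,
#'   `psd_theta_significant`, `itc_theta_early`, `itc_theta_late`,
#'   `itc_theta_significant`.
#' @export
theta_summary <- function(report) {
  th_psd <- report$psd$freq_hz >= 4 & report$psd$freq_hz <= 8
  th_tf <- report$itc$freq_hz >= 4 & report$itc$freq_hz <= 8
  tf_rows <- function(res) {
    matrix(seq_len(length(res$freq_hz) * length(res$time_ms)),
           length(res$freq_hz), length(res$time_ms), byrow = TRUE)[th_tf, ]
  }
  itc_sig <- report$itc$test$significant[as.vector(tf_rows(report$itc))] &
    (as.vector(report$itc$late[th_tf, ]) < as.vector(report$itc$early[th_tf, ]))
  tibble::tibble(
    psd_theta_early = mean(report$psd$early[th_psd]),
    psd_theta_late = mean(report$psd$late[th_psd]),
    psd_theta_significant = any(report$psd$test$significant[th_psd] &
                                  report$psd$test$observed[th_psd] < 0),
    itc_theta_early = mean(report$itc$early[th_tf, ]),
    itc_theta_late = mean(report$itc$late[th_tf, ]),
    itc_theta_significant = any(itc_sig)
  )
}
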