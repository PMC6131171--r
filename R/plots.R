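#' Quick look at a stimulus
#'
#' Renders the stimulus and draws it with ggplot2 (white or red ink on black).
#'
#' @param stimulus A `psicat_target` or `psicat_primer`.
#' @param pixels_per_degree Raster resolution.
#' @param canvas_size Canvas side, degrees.
#' @return A ggplot object.
#' @export
plot_stimulus <- function(stimulus, pixels_per_degree = 32, canvas_size = 10) {
  img <- render_raster(stimulus, pixels_per_degree, canvas_size)
  ink <- attr(img, "ink")
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$v <- as.vector(t(img))
  df$x <- (df$col - 0.5) / pixels_per_degree - canvas_size / 2
  df$y <- canvas_size / 2 - (df$row - 0.5) / pixels_per_degree
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black",
                                 high = if (ink == "red") "red" else "white",
                                 guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "degrees", y = "degrees") +
    ggplot2::theme_minimal()
}

#' Participant-wise RT distributions by condition
#'
#' Box plots of per-participant median RTs across the four primary conditions,
#' ordered congruent SCI, congruent no-SCI, incongruent SCI, incongruent
#' no-SCI.
#'
#' @param summary Output of [summarize_behavior()].
#' @return A ggplot object.
#' @export
plot_rt_conditions <- function(summary) {
  summary$condition <- factor(paste(summary$congruency, summary$target_class,
                                    sep = "."),
                              levels = c("con.SCI", "con.noSCI", "inc.SCI",
                                         "inc.noSCI"))
  ggplot2::ggplot(summary, ggplot2::aes(.data$condition,
                                        .data$median_rt_ms)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "median RT (ms, hit trials)") +
    ggplot2::theme_minimal()
}

#' Plot a spectral result
#'
#' Power spectra as early/late line plots; ERSP and ITC as early/late tile
#' panels with significant bins outlined.
#'
#' @param object A `psicat_spectral` (with a `test` element for masking).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psicat_spectral <- function(object, ...) {
  if (object$kind == "psd") {
    df <- tibble::tibble(freq = rep(object$freq_hz, 2),
                         power = c(object$early, object$late),
                         subset = rep(c("early", "late"),
                                      each = length(object$freq_hz)))
    return(ggplot2::ggplot(df, ggplot2::aes(.data$freq, 10 * log10(.data$power),
                                            colour = .data$subset)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "frequency (Hz)", y = "power (dB)",
                           title = "FM power spectrum, first vs last 10% of trials") +
             ggplot2::theme_minimal())
  }
  grid <- tidyr::expand_grid(freq = object$freq_hz, time = object$time_ms)
  df <- dplyr::bind_rows(
    dplyr::mutate(grid, value = as.vector(t(object$early)), subset = "early"),
    dplyr::mutate(grid, value = as.vector(t(object$late)), subset = "late"))
  if (!is.null(object$test)) {
    df$significant <- rep(object$test$significant, 2)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~subset) +
    ggplot2::scale_fill_viridis_c(name = if (object$kind == "ersp") "dB"
                                  else "ITC") +
    ggplot2::labs(x = "time (ms)", y = "frequency (Hz)",
                  title = toupper(object$kind)) +
    ggplot2::theme_minimal()
  if (!is.null(object$test)) {
    p <- p + ggplot2::geom_point(data = df[df$significant, ],
                                 shape = 4, size = 0.8, colour = "white")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Grand-average ERP curves at an ROI
#'
#' Averages baseline-corrected epochs within condition cells and plots the ROI
#' mean time course.
#'
#' @param epochs A baseline-corrected `psicat_epochs`.
#' @param roi ROI name.
#' @param by Grouping column in `epochs$info` (`"congruency"` or
#'   `"target_class"`).
#' @return A ggplot object.
#' @export
plot_erp_curves <- function(epochs, roi = "vertex", by = "congruency") {
  ch_idx <- match(roi_channels(roi), epochs$channels)
  groups <- unique(epochs$info[[by]])
  df <- purrr::map_dfr(groups, function(g) {
    sel <- which(epochs$info[[by]] == g)
    tibble::tibble(time_ms = epochs$times_ms,
                   uv = apply(epochs$data[sel, ch_idx, , drop = FALSE],
                              3, mean),
                   group = g)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$uv,
                                   colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time re target onset (ms)", y = "amplitude (uV)",
                  colour = by, title = paste("ROI:", roi)) +
    ggplot2::theme_minimal()
}
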