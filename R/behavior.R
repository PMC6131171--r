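#' Per-participant behavioural summary
#'
#' Error trials are removed first; median RT and RT variability (SD of hit
#' RTs) are computed on hits only, per participant and primary condition;
#' error percentage uses all trials. Conditions with no hit trials are flagged
#' missing (NA) and excluded pairwise downstream.
#'
#' @param responses Tibble of trial responses with columns `participant_id`,
#'   `congruency`, `target_class`, `rt_ms`, `correct` (e.g. row-bound
#'   [simulate_responses()] outputs with a `participant_id` added).
#' @return Tibble: `participant_id`, `congruency`, `target_class`,
#'   `median_rt_ms`, `rtv_ms`, `error_pct`, `n_trials`, `n_hits`.
#' @export
summarize_behavior <- function(responses) {
  responses |>
    dplyr::group_by(.data$participant_id, .data$congruency,
                    .data$target_class) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_hits = sum(.data$correct),
      median_rt_ms = ifelse(.data$n_hits > 0,
                            stats::median(.data$rt_ms[.data$correct]),
                            NA_real_),
      rtv_ms = ifelse(.data$n_hits > 1,
                      stats::sd(.data$rt_ms[.data$correct]), NA_real_),
      error_pct = 100 * mean(!.data$correct),
      .groups = "drop")
}

#' One-sided Mann-Whitney U test with z-based effect size
#'
#' Rank-sum U statistic with average ranks for ties; z from the normal
#' approximation with tie-corrected variance and continuity correction; exact
#' p by the null U distribution when both samples have at most `exact_max`
#' observations and there are no ties. `direction = "less"` tests the
#' alternative that `a` is stochastically smaller than `b`. An all-identical
#' pooled sample is degenerate: z = 0, p = 0.5, flagged.
#'
#' A Wilcoxon signed-rank alternative for genuinely paired use is available
#' via `paired = TRUE` (normal approximation z on the signed-rank statistic).
#'
#' @param a,b Numeric samples (length >= 2 each).
#' @param direction `"less"` or `"greater"` (a vs b).
#' @param exact_max Size bound for the exact branch.
#' @param paired Use the Wilcoxon signed-rank test instead.
#' @return One-row tibble: `median_diff` (difference of sample medians,
#'   oriented so the predicted direction is positive), `U`, `z`, `p`,
#'   `exact`, `degenerate`.
#' @export
mann_whitney_one_sided <- function(a, b, direction = c("less", "greater"),
                                   exact_max = 8, paired = FALSE) {
  direction <- match.arg(direction)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  med_diff <- if (direction == "less") {
    stats::median(b) - stats::median(a)
  } else {
    stats::median(a) - stats::median(b)
  }
  if (paired) return(signed_rank_one_sided(a, b, direction, med_diff))
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) {
    return(tibble::tibble(median_diff = med_diff, U = n1 * n2 / 2, z = 0,
                          p = 0.5, exact = FALSE, degenerate = TRUE))
  }
  r <- rank(pooled)
  U_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # small when a < b
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  U <- if (direction == "less") U_a else n1 * n2 - U_a
  if (!has_ties && max(n1, n2) <= exact_max) {
    p <- stats::pwilcox(U, n1, n2)
    mu <- n1 * n2 / 2
    sd0 <- sqrt(n1 * n2 * (N + 1) / 12)
    z <- (U - mu) / sd0
    return(tibble::tibble(median_diff = med_diff, U = U, z = z, p = p,
                          exact = TRUE, degenerate = FALSE))
  }
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sd0 <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
  z <- (U - mu + 0.5) / sd0        # continuity-corrected, lower tail
  p <- stats::pnorm(z)
  tibble::tibble(median_diff = med_diff, U = U, z = z, p = p,
                 exact = FALSE, degenerate = FALSE)
}

signed_rank_one_sided <- function(a, b, direction, med_diff) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n < 2) {
    return(tibble::tibble(median_diff = med_diff, U = NA_real_, z = 0,
                          p = 0.5, exact = FALSE, degenerate = TRUE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])               # large when a > b
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sd0 <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
  z <- if (direction == "greater") (V - mu - 0.5) / sd0
       else -(V - mu + 0.5) / sd0  # oriented so large z favours the direction
  tibble::tibble(median_diff = med_diff, U = V, z = z,
                 p = stats::pnorm(z, lower.tail = FALSE),
                 exact = FALSE, degenerate = FALSE)
}

#' Effect size from a z score
#'
#' `ES = |z| / sqrt(N)`, with N the total number of observations in the test
#' (both samples combined).
#'
#' @param z Test z score.
#' @param N Total observations, >= 1.
#' @return Non-negative effect size.
#' @export
es_from_z <- function(z, N) {
  if (any(N <= 0)) stop("N must be positive", call. = FALSE)
  abs(z) / sqrt(N)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Family-wise error control by the Holm step-down method (monotone, capped at
#' one). Thin wrapper over [stats::p.adjust()].
#'
#' @param p Vector of raw p values.
#' @return Adjusted p values in the input order.
#' @export
holm_bonferroni <- function(p) {
  stats::p.adjust(p, method = "holm")
}

#' Advisory distributional screens
#'
#' Levene-type test for homogeneity of variance (Brown-Forsythe form: one-way
#' ANOVA on absolute deviations from the group medians) and Shapiro-Wilk
#' normality per sample. Advisory only; the rank tests never depend on them.
#'
#' @param a,b Numeric samples.
#' @return One-row tibble: `levene_p`, `shapiro_p_a`, `shapiro_p_b`,
#'   `degenerate`.
#' @export
assumption_screens <- function(a, b) {
  degenerate <- stats::sd(a) == 0 || stats::sd(b) == 0
  if (degenerate) {
    return(tibble::tibble(levene_p = NA_real_, shapiro_p_a = NA_real_,
                          shapiro_p_b = NA_real_, degenerate = TRUE))
  }
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  dev <- c(abs(a - stats::median(a)), abs(b - stats::median(b)))
  lev <- stats::anova(stats::lm(dev ~ g))[["Pr(>F)"]][1]
  tibble::tibble(levene_p = lev,
                 shapiro_p_a = stats::shapiro.test(a)$p.value,
                 shapiro_p_b = stats::shapiro.test(b)$p.value,
                 degenerate = FALSE)
}

behavior_hypotheses <- function() {
  tibble::tribble(
    ~hypothesis, ~comparison,                ~question,
    "H1rt",      "con.SCI < con.noSCI",      "mixed",
    "H1rt",      "con.noSCI < inc.SCI",      "mixed",
    "H1rt",      "inc.SCI < inc.noSCI",      "mixed",
    "H1rtv",     "SCI.rtv < noSCI.rtv",      "sci",
    "H2err",     "con.err < inc.err",        "congruency"
  )
}

#' Behavioural hypothesis battery
#'
#' Runs the study's behavioural tests on participant-wise summaries: the
#' transitive RT chain con.SCI < con.noSCI < inc.SCI < inc.noSCI on median
#' RTs, RT variability SCI < noSCI, and error rate con < inc; each a one-sided
#' Mann-Whitney U test, Holm-adjusted as one family, with ES = |z| / sqrt(N).
#'
#' @param summary Output of [summarize_behavior()].
#' @param paired Use the signed-rank alternative instead of Mann-Whitney.
#' @return Tibble with one row per test: `hypothesis`, `comparison`,
#'   `question`, `median_diff`, `U`, `z`, `p`, `adj_p`, `es`, `N`,
#'   `significant`.
#' @export
analyze_behavior <- function(summary, paired = FALSE) {
  cell <- function(cg, cl, var) {
    x <- summary[summary$congruency == cg & summary$target_class == cl, ]
    x[[var]][order(x$participant_id)]
  }
  by_class <- summary |>
    dplyr::group_by(.data$participant_id, .data$target_class) |>
    dplyr::summarise(rtv_ms = mean(.data$rtv_ms), .groups = "drop")
  by_cong <- summary |>
    dplyr::group_by(.data$participant_id, .data$congruency) |>
    dplyr::summarise(error_pct = stats::weighted.mean(.data$error_pct,
                                                      .data$n_trials),
                     .groups = "drop")
  pull2 <- function(df, col, val, var) {
    x <- df[df[[col]] == val, ]
    x[[var]][order(x$participant_id)]
  }
  pairs <- list(
    list(a = cell("con", "SCI", "median_rt_ms"),
         b = cell("con", "noSCI", "median_rt_ms")),
    list(a = cell("con", "noSCI", "median_rt_ms"),
         b = cell("inc", "SCI", "median_rt_ms")),
    list(a = cell("inc", "SCI", "median_rt_ms"),
         b = cell("inc", "noSCI", "median_rt_ms")),
    list(a = pull2(by_class, "target_class", "SCI", "rtv_ms"),
         b = pull2(by_class, "target_class", "noSCI", "rtv_ms")),
    list(a = pull2(by_cong, "congruency", "con", "error_pct"),
         b = pull2(by_cong, "congruency", "inc", "error_pct"))
  )
  res <- purrr::map2_dfr(seq_len(nrow(behavior_hypotheses())), pairs,
                         function(i, pr) {
    mw <- mann_whitney_one_sided(pr$a, pr$b, "less", paired = paired)
    dplyr::bind_cols(behavior_hypotheses()[i, ], mw,
                     tibble::tibble(N = length(pr$a) + length(pr$b)))
  })
  res$adj_p <- holm_bonferroni(res$p)
  res$es <- es_from_z(res$z, res$N)
  res$significant <- res$adj_p <= 0.05
  res
}

#' Check the transitive RT ordering
#'
#' Verifies, test by test, the RT chain con.SCI < con.noSCI < inc.SCI <
#' inc.noSCI on group medians of the participant-wise medians.
#'
#' @param summary Output of [summarize_behavior()].
#' @return Logical scalar; attribute `medians` carries the four group medians.
#' @export
check_rt_ordering <- function(summary) {
  med <- summary |>
    dplyr::group_by(.data$congruency, .data$target_class) |>
    dplyr::summarise(m = stats::median(.data$median_rt_ms, na.rm = TRUE),
                     .groups = "drop")
  key <- paste(med$congruency, med$target_class, sep = ".")
  m <- stats::setNames(med$m, key)
  ord <- m[["con.SCI"]] < m[["con.noSCI"]] &&
    m[["con.noSCI"]] < m[["inc.SCI"]] &&
    m[["inc.SCI"]] < m[["inc.noSCI"]]
  structure(ord, medians = m)
}
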