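#' Assemble effect-size records from test batteries
#'
#' Builds the tagged effect-size records that feed the headline effect-size
#' comparison: behavioural rank-test effect sizes (|z|/sqrt(N) estimator) and
#' neural windowed-amplitude effect sizes (d-from-t estimator), each tagged
#' with its family and question (congruency vs gestalt/SCI). The transitive RT
#' chain mixes both manipulations, so its rows carry the question tag
#' `"mixed"` and never enter a pooled cell.
#'
#' @param behavior Output of [analyze_behavior()].
#' @param erp Output of [erp_test_battery()].
#' @return Tibble of class `psicat_es_records`: `hypothesis`, `stratum`,
#'   `family`, `question`, `estimator`, `es`, `significant`.
#' @export
collect_es_records <- function(behavior = NULL, erp = NULL) {
  rows <- list()
  if (!is.null(behavior)) {
    rows <- c(rows, list(tibble::tibble(
      hypothesis = behavior$hypothesis,
      stratum = NA_character_,
      family = "behavioural",
      question = behavior$question,
      estimator = "r_from_z",
      es = behavior$es,
      significant = behavior$significant)))
  }
  if (!is.null(erp)) {
    question <- ifelse(erp$hypothesis %in% c("H3P3a", "H3P3b"),
                       "congruency", "sci")
    rows <- c(rows, list(tibble::tibble(
      hypothesis = erp$hypothesis,
      stratum = erp$stratum,
      family = "neural",
      question = question,
      estimator = "d_from_t",
      es = erp$es,
      significant = erp$significant)))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("psicat_es_records", class(out))
  out
}

#' Pooled median absolute effect size for one family/question cell
#'
#' Median of |ES| over the cell's significant records only, reported to two
#' decimals with half-away-from-zero rounding. A cell never mixes effect-size
#' estimators (asserted on the record tags). An empty cell gives NA.
#'
#' @param records A [collect_es_records()] tibble.
#' @param family `"behavioural"` or `"neural"`.
#' @param question `"congruency"` or `"sci"`.
#' @return Scalar median |ES| (2 d.p.), or NA if the cell is empty.
#' @export
pool_median_abs <- function(records, family, question) {
  cell <- records[records$family == family & records$question == question &
                    records$significant & !is.na(records$es), ]
  if (nrow(cell) == 0) return(NA_real_)
  if (length(unique(cell$estimator)) > 1) {
    stop("effect-size estimators may not be mixed within a pooled cell",
         call. = FALSE)
  }
  round_half_up(stats::median(abs(cell$es)), 2)
}

#' Nominal effect-size label
#'
#' Rule-of-thumb labels for Cohen's-d-scale magnitudes, extended above
#' "large": >= 2.0 huge, >= 1.2 very large, >= 0.8 large, >= 0.5 medium,
#' >= 0.2 small, >= 0.01 very small, else negligible (closed lower bounds).
#'
#' @param es_abs Absolute effect size(s).
#' @return Character vector of labels.
#' @export
nominal_label <- function(es_abs) {
  cut(abs(es_abs),
      breaks = c(-Inf, 0.01, 0.2, 0.5, 0.8, 1.2, 2.0, Inf),
      labels = c("negligible", "very small", "small", "medium", "large",
                 "very large", "huge"),
      right = FALSE) |> as.character()
}

#' Headline effect-size verdict
#'
#' For each family, pools the significant absolute effect sizes of the
#' congruency question and of the gestalt (SCI vs no-SCI) question, takes
#' medians and nominal labels, and checks the headline inequality: congruency
#' effects larger than gestalt effects. The overall verdict is true only if
#' the inequality holds in every family with both cells computable.
#'
#' @param records A [collect_es_records()] tibble.
#' @return List of class `psicat_hes`: `by_family` tibble (`family`,
#'   `sci_median`, `congruency_median`, `sci_label`, `congruency_label`,
#'   `satisfied`), `verdict` (logical; NA when any cell is missing), and
#'   `records`.
#' @export
hes_verdict <- function(records) {
  fams <- unique(records$family)
  by_family <- purrr::map_dfr(fams, function(fam) {
    sci <- pool_median_abs(records, fam, "sci")
    con <- pool_median_abs(records, fam, "congruency")
    tibble::tibble(family = fam,
                   sci_median = sci, congruency_median = con,
                   sci_label = nominal_label(sci),
                   congruency_label = nominal_label(con),
                   satisfied = if (is.na(sci) || is.na(con)) NA
                               else con > sci)
  })
  verdict <- if (any(is.na(by_family$satisfied))) NA
             else all(by_family$satisfied)
  structure(list(by_family = by_family, verdict = verdict,
                 records = records),
            class = "psicat_hes")
}

#' @export
print.psicat_hes <- function(x, ...) {
  cat("Headline effect-size comparison (congruency vs gestalt questions)\n")
  print(x$by_family)
  cat("Overall verdict (congruency > gestalt in every family): ",
      ifelse(is.na(x$verdict), "incomputable (missing cell)", x$verdict),
      "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a headline effect-size verdict
#'
#' @param x A `psicat_hes`.
#' @param ... Unused.
#' @return The per-family tibble.
#' @export
tidy.psicat_hes <- function(x, ...) x$by_family

#' One-row summary of a headline effect-size verdict
#'
#' @param x A `psicat_hes`.
#' @param ... Unused.
#' @return One-row tibble: `n_records`, `n_significant`, `verdict`.
#' @export
glance.psicat_hes <- function(x, ...) {
  tibble::tibble(n_records = nrow(x$records),
                 n_significant = sum(x$records$significant),
                 verdict = x$verdict)
}
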