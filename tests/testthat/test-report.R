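published_records <- function() {
  # Table-shaped inputs: behavioural rank-test ES and neural d-from-t ES with
  # their significance flags
  behav <- tibble::tibble(
    hypothesis = c("H1rt", "H1rt", "H1rt", "H1rtv", "H2err"),
    question = c("mixed", "mixed", "mixed", "sci", "congruency"),
    es = c(0.99, 0.51, 0.64, 0.57, 0.97),
    significant = TRUE)
  erp <- tibble::tibble(
    hypothesis = c("H3P3a", "H3P3b", "H4pN1", "H4tN1", "H4tN1", "H4tP3a",
                   "H4tP3a"),
    stratum = c(NA, NA, NA, "con", "inc", "con", "inc"),
    es = c(2.29, -1.94, -1.54, NA, -1.05, 0.79, 0.60),
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  collect_es_records(behav, erp)
}

test_that("pooled medians reproduce the published family comparison", {
  rec <- published_records()
  expect_equal(pool_median_abs(rec, "neural", "congruency"), 2.12)
  expect_equal(pool_median_abs(rec, "neural", "sci"), 1.05)
  expect_equal(pool_median_abs(rec, "behavioural", "congruency"), 0.97)
  expect_equal(pool_median_abs(rec, "behavioural", "sci"), 0.57)
})

test_that("only significant records enter a pool", {
  rec <- published_records()
  # toggling one record's significance changes the pool size by one
  n_before <- sum(rec$family == "neural" & rec$question == "sci" &
                    rec$significant)
  rec2 <- rec
  rec2$significant[rec2$hypothesis == "H4tP3a" & rec2$stratum == "inc"] <- TRUE
  n_after <- sum(rec2$family == "neural" & rec2$question == "sci" &
                   rec2$significant)
  expect_equal(n_after, n_before + 1)
  expect_equal(pool_median_abs(rec2, "neural", "sci"),
               round(median(c(1.54, 1.05, 0.79, 0.60)), 2))
  # single-record pool is that record
  one <- rec[rec$hypothesis == "H1rtv", ]
  expect_equal(pool_median_abs(one, "behavioural", "sci"), 0.57)
  # empty cell gives NA
  none <- rec[rec$significant == FALSE, ]
  expect_true(is.na(pool_median_abs(none, "behavioural", "sci")))
})

test_that("estimator purity is enforced within a pooled cell", {
  rec <- published_records()
  bad <- rec
  bad$estimator[1] <- "d_from_t"
  bad$question[1] <- "sci"
  bad$family[1] <- "behavioural"
  expect_error(pool_median_abs(bad, "behavioural", "sci"), "mixed")
})

test_that("nominal labels follow the extended rule-of-thumb thresholds", {
  expect_equal(nominal_label(0.57), "medium")
  expect_equal(nominal_label(2.12), "huge")
  expect_equal(nominal_label(0.97), "large")
  expect_equal(nominal_label(1.05), "large")
  expect_equal(nominal_label(0.8), "large")      # closed lower bound
  expect_equal(nominal_label(c(0.005, 0.1, 0.3, 1.3)),
               c("negligible", "very small", "small", "very large"))
})

test_that("the verdict holds on the published inputs and fails when equal", {
  v <- hes_verdict(published_records())
  expect_true(v$verdict)
  expect_equal(v$by_family$congruency_label, c("large", "huge"))
  expect_equal(v$by_family$sci_label, c("medium", "large"))
  eq <- collect_es_records(
    tibble::tibble(hypothesis = c("H1rtv", "H2err"),
                   question = c("sci", "congruency"),
                   es = c(0.5, 0.5), significant = TRUE))
  expect_false(hes_verdict(eq)$verdict)
})

test_that("a missing cell yields an explicit incomputable verdict", {
  rec <- collect_es_records(
    tibble::tibble(hypothesis = "H2err", question = "congruency",
                   es = 0.9, significant = TRUE))
  v <- hes_verdict(rec)
  expect_true(is.na(v$verdict))
  expect_true(is.na(v$by_family$sci_median))
  expect_equal(nrow(tidy(v)), 1)
  expect_true(is.na(glance(v)$verdict))
})

test_that("mixed-question records never enter a pooled cell", {
  rec <- published_records()
  expect_false(any(rec$question == "mixed" &
                     rec$hypothesis %in% c("H1rtv", "H2err")))
  expect_equal(pool_median_abs(rec, "behavioural", "congruency"), 0.97)
})
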