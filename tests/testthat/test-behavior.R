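test_that("behavioural summaries use hit trials only", {
  resp <- tibble::tibble(
    participant_id = 0,
    congruency = "con", target_class = "SCI",
    rt_ms = c(400, 400, 400, 900),
    correct = c(TRUE, TRUE, TRUE, FALSE))
  s <- summarize_behavior(resp)
  expect_equal(s$median_rt_ms, 400)
  expect_equal(s$rtv_ms, 0)
  expect_equal(s$error_pct, 25)
  # 1 error in 100 trials -> 1.0%
  resp2 <- tibble::tibble(participant_id = 0, congruency = "inc",
                          target_class = "SCI",
                          rt_ms = rnorm(100, 500, 10),
                          correct = c(FALSE, rep(TRUE, 99)))
  expect_equal(summarize_behavior(resp2)$error_pct, 1.0)
})

test_that("Mann-Whitney exact branch enumerates the 2v2 case", {
  r <- mann_whitney_one_sided(c(1, 2), c(3, 4), "less")
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 6)
  expect_true(r$exact)
})

test_that("identical samples give the degenerate symmetric result", {
  r <- mann_whitney_one_sided(rep(2, 5), rep(2, 5))
  expect_equal(r$z, 0)
  expect_equal(r$p, 0.5)
  expect_true(r$degenerate)
})

test_that("Mann-Whitney agrees with wilcox.test as the oracle", {
  withr::local_seed(10)
  for (i in 1:20) {
    a <- rnorm(17); b <- rnorm(17, 0.5)
    mine <- mann_whitney_one_sided(a, b, "less")
    ref <- suppressWarnings(wilcox.test(a, b, alternative = "less",
                                        exact = FALSE, correct = TRUE))
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
  # tied data
  a <- c(1, 2, 2, 3, 5, 5, 6, 8, 9, 9)
  b <- c(2, 4, 5, 5, 7, 8, 9, 10, 11, 11)
  mine <- mann_whitney_one_sided(a, b, "less")
  ref <- suppressWarnings(wilcox.test(a, b, alternative = "less",
                                      exact = FALSE, correct = TRUE))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
})

test_that("rank-test type-I error stays near nominal alpha under the null", {
  withr::local_seed(11)
  rej <- mean(replicate(4000,
    mann_whitney_one_sided(rnorm(17), rnorm(17))$p <= 0.05))
  expect_gt(rej, 0.04)
  expect_lt(rej, 0.06)
})

test_that("effect size from z follows |z|/sqrt(N)", {
  expect_equal(es_from_z(1.96, 4), 0.98)
  expect_equal(es_from_z(0, 10), 0)
  expect_equal(es_from_z(3, 9), 1)
  expect_equal(es_from_z(-3, 9), 1)
  expect_error(es_from_z(1, 0), "positive")
})

test_that("Holm adjustment matches hand-computed step-down values", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(holm_bonferroni(c(0.5, 0.9)), c(1.0, 1.0))
  p <- c(0.001, 0.02, 0.04, 0.3)
  expect_true(all(holm_bonferroni(p) >= p))
})

test_that("assumption screens flag skew and degeneracy but never block", {
  withr::local_seed(12)
  sk <- assumption_screens(exp(rnorm(50, 0, 1)), rnorm(50))
  expect_lt(sk$shapiro_p_a, 0.05)
  eq <- assumption_screens(rnorm(50), rnorm(50))
  expect_gt(eq$levene_p, 0.001)
  dg <- assumption_screens(rep(1, 10), rnorm(10))
  expect_true(dg$degenerate)
})

test_that("signed-rank alternative runs behind the paired flag", {
  withr::local_seed(13)
  a <- rnorm(17); b <- a + 0.8 + rnorm(17, 0, 0.3)
  r <- mann_whitney_one_sided(a, b, "less", paired = TRUE)
  expect_lt(r$p, 0.01)
  expect_gt(r$z, 2)
})

test_that("the behavioural battery reports the transitive chain columns", {
  withr::local_seed(14)
  bm <- default_behavior_model()
  resp <- purrr::map_dfr(0:7, function(p) {
    sched <- fast_schedule(seed = p + 1, trials_per_block = 80,
                           participant_index = p)
    pm <- participant_behavior(bm, seed = p + 100)
    dplyr::mutate(simulate_responses(sched, pm, seed = p + 200),
                  participant_id = p)
  })
  summ <- summarize_behavior(resp)
  res <- analyze_behavior(summ)
  expect_equal(nrow(res), 5)
  expect_true(all(res$adj_p >= res$p))
  expect_true(all(res$es >= 0 & res$es <= 1))
  expect_true(check_rt_ordering(summ))
})
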