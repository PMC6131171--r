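test_that("default schedule has the protocol's published shape", {
  s <- build_schedule(seed = 1)
  expect_equal(nrow(s$trials), 550)
  expect_equal(length(unique(s$trials$block)), 5)
  expect_true(all(table(s$trials$block) == 110))
  cells <- unique(s$trials[, c("congruency", "target_class", "n_vertices")])
  expect_equal(nrow(cells), 8)
  expect_true(all(s$trials$iti_ms >= 400 & s$trials$iti_ms <= 600))
})

test_that("conditions are drawn uniformly over the eight cells", {
  s <- build_schedule(seed = 7, n_blocks = 10, trials_per_block = 1000)
  counts <- table(paste(s$trials$congruency, s$trials$target_class,
                        s$trials$n_vertices))
  n <- nrow(s$trials)
  se <- sqrt(n * (1 / 8) * (7 / 8))
  expect_true(all(abs(counts - n / 8) <= 3 * se))
})

test_that("trial timing follows fixation 100 ms and primer 150 ms", {
  s <- build_schedule(seed = 2)
  expect_equal(s$trials$primer_onset_ms - s$trials$fixation_onset_ms,
               rep(100, 550))
  expect_equal(s$trials$target_onset_ms - s$trials$primer_onset_ms,
               rep(150, 550))
  # mean trial duration identity: 100 + 150 + R + mean ITI
  r <- 750
  sched_r <- realize_timeline(s, tibble::tibble(rt_ms = rep(r, 550)))
  durations <- diff(sched_r$trials$fixation_onset_ms[1:110])
  expect_equal(mean(durations), 100 + 150 + r + mean(s$trials$iti_ms[1:109]),
               tolerance = 1e-9)
})

test_that("practice schedule is 12 trials, three per primary condition", {
  p <- build_practice(seed = 3)
  expect_equal(nrow(p$trials), 12)
  counts <- table(p$trials$congruency, p$trials$target_class)
  expect_true(all(counts == 3))
  expect_identical(build_practice(seed = 3)$trials, p$trials)
  expect_false(identical(build_practice(seed = 4)$trials$congruency,
                         p$trials$congruency) &&
                 identical(build_practice(seed = 4)$trials$target_class,
                           p$trials$target_class))
})

test_that("response hands alternate by participant parity", {
  expect_equal(assign_response_hands(0)[["SCI"]], "right")
  expect_equal(assign_response_hands(1)[["SCI"]], "left")
  hands <- vapply(0:9, function(i) assign_response_hands(i)[["SCI"]],
                  character(1))
  expect_equal(sum(hands == "left"), 5)
})

test_that("events export carries the protocol timing and round-trips", {
  s <- fast_schedule(seed = 5)
  resp <- simulate_responses(s, seed = 5)
  s <- realize_timeline(s, resp)
  ev <- export_events(s, resp)
  primers <- ev[ev$event_type == "primer", ]
  targets <- ev[ev$event_type == "target", ]
  fix <- ev[ev$event_type == "fixation", ]
  expect_equal(primers$duration, rep(0.150, nrow(primers)))
  expect_equal(targets$onset - primers$onset, rep(0.150, nrow(primers)))
  expect_equal(primers$onset - fix$onset, rep(0.100, nrow(primers)))
  d <- withr::local_tempdir()
  f <- file.path(d, "events.tsv")
  write_events(ev, f)
  expect_equal(as.data.frame(read_events(f)), as.data.frame(ev))
})

test_that("schedules are reproducible per seed", {
  expect_identical(build_schedule(seed = 11)$trials,
                   build_schedule(seed = 11)$trials)
})
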