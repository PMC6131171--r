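test_that("ex-Gaussian calibration hits the published medians and spreads", {
  m <- default_behavior_model()
  withr::local_seed(42)
  for (i in seq_len(nrow(m$conditions))) {
    x <- rexgauss(50000, m$conditions$mu[i], m$conditions$sigma[i],
                  m$conditions$tau[i])
    expect_lt(abs(median(x) - m$conditions$median_ms[i]), 5)
    expect_lt(abs(sd(x) - m$conditions$sd_ms[i]), 3)
  }
})

test_that("error probabilities match the published per-condition rates", {
  sched <- build_schedule(seed = 1, n_blocks = 50, trials_per_block = 8000)
  resp <- simulate_responses(sched, seed = 2)
  err <- tapply(!resp$correct, paste(resp$congruency, resp$target_class),
                mean) * 100
  expect_lt(abs(err[["inc SCI"]] - 2.0), 0.2)
  expect_lt(abs(err[["con SCI"]] - 0.7), 0.2)
  expect_lt(abs(err[["con noSCI"]] - 0.7), 0.2)
  expect_lt(abs(err[["inc noSCI"]] - 0.8), 0.2)
})

test_that("degenerate behaviour models behave deterministically", {
  sched <- fast_schedule(seed = 1)
  m <- default_behavior_model()
  m$conditions$sigma <- 1e-9
  m$conditions$tau <- 1e-9
  m$conditions$error_prob <- 0
  m$lapse_prob <- 0
  resp <- simulate_responses(sched, m, seed = 1)
  mu <- m$conditions$mu[match(paste(resp$congruency, resp$target_class),
                              paste(m$conditions$congruency,
                                    m$conditions$target_class))]
  expect_equal(resp$rt_ms, mu, tolerance = 1e-6)
  expect_true(all(resp$correct))
  expect_identical(simulate_responses(sched, m, seed = 1), resp)
})

test_that("responses map the correct button through the hand assignment", {
  sched <- fast_schedule(seed = 2, participant_index = 0)   # SCI -> right
  m <- default_behavior_model()
  m$conditions$error_prob <- 0
  m$lapse_prob <- 0
  resp <- simulate_responses(sched, m, seed = 3)
  expect_true(all(resp$button[resp$target_class == "SCI"] == "right"))
  expect_true(all(resp$button[resp$target_class == "noSCI"] == "left"))
})

test_that("a noiseless single-component recording reproduces its amplitude", {
  sched <- fast_schedule(seed = 4, trials_per_block = 12)
  resp <- simulate_responses(sched, seed = 4)
  nm <- default_neural_model()
  nm$noise$rms_uv <- 1e-12
  nm$theta$induced_rms_early <- 0; nm$theta$induced_rms_late <- 0
  nm$theta$evoked_amp_early <- 0; nm$theta$evoked_amp_late <- 0
  # single active component: P3b only
  nm$peaks$peak_uv[nm$peaks$component != "P3b"] <- 0
  nm$peaks$peak_uv[nm$peaks$component == "P3b"] <- 5
  ses <- simulate_recording(sched, resp, nm, seed = 4)
  ep <- baseline_correct(epoch_recording(ses), "trial")
  amp <- roi_window_amplitude(ep, "parietal", "P3b", by = "congruency")
  g <- mean(exp(-(psicat:::epoch_times_ms(512)[
    abs(psicat:::epoch_times_ms(512) - 480) <= 20] - 480)^2 / (2 * 50.96^2)))
  expect_equal(amp$mean_uv, rep(5 * g, 2), tolerance = 0.01)
})

test_that("event markers are strictly increasing and cover every trial", {
  ses <- tiny_session(seed = 6)
  targets <- ses$events[ses$events$event_type == "target", ]
  expect_equal(nrow(targets), nrow(ses$responses))
  expect_true(all(diff(ses$events$onset[ses$events$event_type == "target"]) > 0))
  expect_equal(nrow(ses$responses), nrow(ses$schedule$trials))
})

test_that("zero theta slopes leave early and late theta power comparable", {
  sched <- build_schedule(seed = 7, n_blocks = 2, trials_per_block = 60)
  resp <- simulate_responses(sched, seed = 7)
  nm <- default_neural_model()
  nm$theta$induced_rms_late <- nm$theta$induced_rms_early
  nm$theta$evoked_amp_late <- nm$theta$evoked_amp_early
  ses <- simulate_recording(sched, resp, nm, seed = 7)
  ep <- epoch_recording(ses, hits_only = FALSE)
  subs <- subset_epochs(ep)
  psd <- psd_subsets(ep, subs)
  th <- psd$freq_hz >= 4 & psd$freq_hz <= 8
  ratio <- mean(psd$late[th]) / mean(psd$early[th])
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 1.6)
})

test_that("simulation is seed-deterministic end to end", {
  a <- tiny_session(seed = 9)
  b <- tiny_session(seed = 9)
  expect_identical(a$eeg, b$eeg)
  expect_identical(a$responses, b$responses)
})
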