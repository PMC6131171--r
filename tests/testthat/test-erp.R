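test_that("the high-pass removes DC, keeps 10 Hz, and is linear-phase", {
  fs <- 512
  h <- psicat:::highpass_kernel(fs)
  expect_equal(length(h), 1.5 * fs + 1)
  expect_equal(h, rev(h), tolerance = 1e-12)     # symmetric -> linear phase
  expect_lt(abs(sum(h)), 0.01)                   # DC gain ~ 0
  x <- sin(2 * pi * 10 * (0:99999) / fs)
  y <- psicat:::apply_fir_centered(x, h)
  mid <- 5000:95000
  expect_lt(abs(sd(y[mid]) / sd(x[mid]) - 1), 0.01)
  dc <- psicat:::apply_fir_centered(rep(1, 10000), h)
  expect_lt(max(abs(dc[3000:7000])), 0.01)
  expect_error(highpass(matrix(rnorm(200), 1), fs = fs), "shorter")
})

test_that("epochs span 384 samples with target onset at the 0 ms sample", {
  ses <- tiny_session(seed = 1)
  ep <- epoch_recording(ses)
  expect_equal(dim(ep$data)[3], 384)
  expect_equal(sum(ep$times_ms == 0), 1)
  expect_equal(which(ep$times_ms == 0), round(0.25 * 512) + 1)
  expect_equal(range(ep$times_ms)[1], -250)
})

test_that("hits_only epoching drops exactly the error trials", {
  ses <- tiny_session(seed = 2)
  n_err <- sum(!ses$responses$correct)
  ep_all <- epoch_recording(ses, hits_only = FALSE)
  ep_hits <- epoch_recording(ses, hits_only = TRUE)
  expect_equal(dim(ep_all$data)[1] - dim(ep_hits$data)[1], n_err)
  expect_true(all(ep_hits$info$correct))
})

test_that("baseline correction zeroes the active window to 1e-9", {
  ses <- tiny_session(seed = 3)
  ep <- epoch_recording(ses)
  for (mode in c("trial", "target")) {
    bc <- baseline_correct(ep, mode)
    win <- psicat:::baseline_window_ms(mode)
    idx <- which(bc$times_ms >= win[1] & bc$times_ms <= win[2])
    bl <- apply(bc$data[, , idx, drop = FALSE], c(1, 2), mean)
    expect_lt(max(abs(bl)), 1e-9)
    expect_identical(bc$baseline_mode, mode)
  }
  # constant epochs become all-zero under either mode
  epc <- synthetic_epochs(4, c("A1", "C20"), function(t, e) rep(5, length(t)))
  expect_lt(max(abs(baseline_correct(epc, "trial")$data)), 1e-12)
  # the two modes differ by a per-epoch, per-channel constant
  d <- baseline_correct(ep, "trial")$data - baseline_correct(ep, "target")$data
  spread <- apply(d, c(1, 2), function(x) diff(range(x)))
  expect_lt(max(spread), 1e-9)
  expect_error(baseline_correct(ep, "whole"), "arg")
})

test_that("the 20 Hz low-pass has the specified band behaviour", {
  mk <- function(f) synthetic_epochs(2, "C20",
                                     function(t, e) sin(2 * pi * f * t / 1000))
  g <- function(f) {
    y <- lowpass20(mk(f))$data[1, 1, ]
    x <- mk(f)$data[1, 1, ]
    sd(y[100:284]) / sd(x[100:284])
  }
  expect_lt(g(30), 0.5)
  expect_gt(g(5), 0.95)
  expect_lt(g(5), 1.05)
  dc <- lowpass20(synthetic_epochs(1, "C20", function(t, e) rep(2, length(t))))
  expect_equal(mean(dc$data[1, 1, 100:284]), 2, tolerance = 0.01)
})

test_that("windowed ROI amplitude is exact on constants and linear in offsets", {
  ep <- synthetic_epochs(8, roi_channels("vertex"),
                         function(t, e) rep(2, length(t)))
  amp <- roi_window_amplitude(ep, "vertex", "P3a", by = "congruency")
  expect_equal(amp$mean_uv, rep(2, 2))
  ep_shift <- ep
  ep_shift$data <- ep$data + 1.5
  amp2 <- roi_window_amplitude(ep_shift, "vertex", "P3a", by = "congruency")
  expect_equal(amp2$mean_uv, amp$mean_uv + 1.5)
  expect_error(roi_window_amplitude(ep, "vertex", "nope"), "unknown component")
})

test_that("one-tailed paired t behaves at the null, the limit, and wrong sign", {
  a <- c(1, 2, 3, 4, 5)
  r0 <- paired_t_one_tailed(a, a + rnorm(5, 0, 1e-12), "greater")
  expect_true(r0$degenerate || abs(r0$t) < 1)
  withr::local_seed(20)
  b <- a + 1 + rnorm(5, 0, 0.01)
  r1 <- paired_t_one_tailed(b, a, "greater")
  expect_lt(r1$p, 1e-4)
  expect_equal(r1$df, 4)
  r2 <- paired_t_one_tailed(a, b, "greater")   # effect in the wrong direction
  expect_gt(r2$p, 0.5)
  rej <- mean(replicate(4000,
    paired_t_one_tailed(rnorm(17), rnorm(17), "greater")$p <= 0.05))
  expect_gt(rej, 0.04)
  expect_lt(rej, 0.06)
})

test_that("d-from-t conversion reproduces the published effect sizes", {
  expect_equal(round(es_from_t(6.68, 17), 2), 2.29)
  expect_equal(round(es_from_t(-3.06, 17), 2), -1.05)
  expect_equal(es_from_t(0, 17), 0)
  expect_error(es_from_t(1, 0), "positive")
})

test_that("epoch rejection drops epochs beyond the amplitude threshold", {
  ep <- synthetic_epochs(6, "C20", function(t, e) {
    if (e == 3) rep(150, length(t)) else rep(1, length(t))
  })
  kept <- reject_epochs(ep, threshold_uv = 100)
  expect_equal(dim(kept$data)[1], 5)
  expect_false(3 %in% kept$info$trial_index)
})
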