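test_that("epoch subsets take disjoint first/last fractions", {
  ep550 <- synthetic_epochs(550, "C20", function(t, e) rnorm(length(t)))
  s <- subset_epochs(ep550)
  expect_equal(s$n_each, 55)
  expect_length(intersect(s$early, s$late), 0)
  ep100 <- synthetic_epochs(100, "C20", function(t, e) rnorm(length(t)))
  s2 <- subset_epochs(ep100)
  expect_equal(s2$n_each, 10)
  ep20 <- synthetic_epochs(20, "C20", function(t, e) rnorm(length(t)))
  expect_error(subset_epochs(ep20), "too small")
})

test_that("the Welch spectrum peaks at the driving frequency", {
  fm <- roi_channels("frontomedial")
  ep <- synthetic_epochs(20, fm, function(t, e) sin(2 * pi * 10 * t / 1000))
  psd <- psd_subsets(ep, make_subsets(20), roi = "frontomedial")
  expect_equal(psd$freq_hz[which.max(psd$early)], 10, tolerance = 0.7)
  # Parseval-style check: band power tracks time-domain variance
  withr::local_seed(30)
  epn <- synthetic_epochs(24, fm, function(t, e) rnorm(length(t)))
  psdn <- psd_subsets(epn, make_subsets(24), roi = "frontomedial")
  # white noise: flat spectrum (no strong linear trend in log power)
  fit <- lm(log(psdn$early) ~ psdn$freq_hz)
  expect_lt(abs(coef(fit)[2]), 0.02)
})

test_that("ERSP is ~0 dB for stationary signals, ~3 dB for doubled power", {
  withr::local_seed(31)
  for (f in c(6, 10)) {
    ep0 <- synthetic_epochs(40, "C20", function(t, e)
      cos(2 * pi * f * t / 1000 + runif(1, 0, 2 * pi)))
    er0 <- ersp_subsets(ep0, make_subsets(40), freqs = f)
    expect_lt(max(abs(er0$early)), 0.6)
    ep2 <- synthetic_epochs(40, "C20", function(t, e) {
      gain <- ifelse(t >= 0, sqrt(2), 1)
      gain * cos(2 * pi * f * t / 1000 + runif(1, 0, 2 * pi))
    })
    er2 <- ersp_subsets(ep2, make_subsets(40), freqs = f)
    late_cols <- as.character(seq(100, 300, 20))
    expect_equal(mean(er2$early[1, late_cols]), 3.01, tolerance = 0.35)
  }
})

test_that("pooled ERSP baseline is invariant to swapping subset labels", {
  withr::local_seed(32)
  ep <- synthetic_epochs(40, "C20", function(t, e) rnorm(length(t)))
  s <- make_subsets(40)
  swapped <- structure(list(early = s$late, late = s$early, n_each = s$n_each),
                       class = "psicat_subsets")
  a <- ersp_subsets(ep, s)
  b <- ersp_subsets(ep, swapped)
  expect_equal(a$early, b$late, tolerance = 1e-9)
  expect_equal(a$late, b$early, tolerance = 1e-9)
})

test_that("ITC is 1 for locked epochs, ~0.886/sqrt(n) for random phase", {
  ep1 <- synthetic_epochs(30, "C20", function(t, e)
    cos(2 * pi * 8 * t / 1000))
  itc1 <- itc_subsets(ep1, make_subsets(30), freqs = 8)
  expect_equal(min(itc1$early), 1, tolerance = 1e-6)
  expect_true(all(itc1$early <= 1 + 1e-9))
  withr::local_seed(33)
  itc_means <- replicate(4, {
    epr <- synthetic_epochs(110, "C20", function(t, e) rnorm(length(t)))
    m <- itc_subsets(epr, make_subsets(110))$early
    stopifnot(all(m <= 1))
    mean(m)
  })
  expect_equal(mean(itc_means), 0.886 / sqrt(55), tolerance = 0.15)
})

test_that("permutation testing is calibrated, sensitive, and deterministic", {
  withr::local_seed(34)
  # type-I: identical distributions, many bins
  rej <- replicate(10, {
    v <- matrix(rnorm(40 * 60), 40, 60)
    attr(v, "labels") <- rep(c("early", "late"), each = 30)
    mean(permutation_test(v, n_perm = 400, alpha = 0.05,
                          seed = sample.int(1e6, 1))$significant)
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
  # sensitivity: one bin with a strong late increase
  v <- matrix(rnorm(5 * 60), 5, 60)
  v[3, 31:60] <- v[3, 31:60] + 3
  attr(v, "labels") <- rep(c("early", "late"), each = 30)
  res <- permutation_test(v, n_perm = 400, seed = 7)
  expect_true(res$significant[3])
  expect_identical(permutation_test(v, n_perm = 400, seed = 7), res)
  expect_error(permutation_test(v, labels = rep("early", 60)), "constant")
  expect_warning(permutation_test(v, n_perm = 50, seed = 1), "coarse")
})

test_that("stability reports per-bin significant fractions over repeats", {
  withr::local_seed(35)
  v <- matrix(rnorm(4 * 60), 4, 60)
  v[2, 31:60] <- v[2, 31:60] + 3
  attr(v, "labels") <- rep(c("early", "late"), each = 30)
  frac <- stability(function(s) permutation_test(v, n_perm = 200,
                                                 seed = s)$significant,
                    repeats = 10, seed = 1)
  expect_equal(frac[2], 1)
  expect_true(all(frac[-2] <= 0.3))
  expect_identical(frac,
                   stability(function(s) permutation_test(v, n_perm = 200,
                                                          seed = s)$significant,
                             repeats = 10, seed = 1))
})

test_that("a theta-ramp session shows the late power rise and ITC drop", {
  sched <- build_schedule(seed = 40)
  resp <- simulate_responses(sched, seed = 40)
  ses <- simulate_recording(sched, resp, default_neural_model(), seed = 40)
  ep <- epoch_recording(ses, hits_only = FALSE)
  rep_ <- analyze_spectral(ep, n_perm = 300, seed = 40)
  th <- theta_summary(rep_)
  expect_gt(th$psd_theta_late, th$psd_theta_early)
  expect_true(th$psd_theta_significant)
  expect_lt(th$itc_theta_late, th$itc_theta_early)
})
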