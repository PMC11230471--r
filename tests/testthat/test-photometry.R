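test_that("sliding-percentile baseline matches the brute-force oracle and edge cases", {
  fs <- 100
  expect_equal(sliding_percentile_baseline(rep(7, 500), fs, 5, 10),
               rep(7, 500))
  # step trace: locality far from the step
  x <- c(rep(0, 1000), rep(10, 1000))
  b <- sliding_percentile_baseline(x, fs, 2, 10)
  expect_equal(b[1:800], rep(0, 800))
  expect_equal(b[1201:2000], rep(10, 800))
  # oracle equivalence on random traces with varying windows/percentiles
  set.seed(42)
  for (k in 1:5) {
    n <- sample(200:1500, 1)
    x <- cumsum(rnorm(n)) + rnorm(n)
    w <- runif(1, 0.5, 4)
    p <- sample(c(5, 10, 50, 90), 1)
    expect_equal(sliding_percentile_baseline(x, fs, w, p),
                 brute_percentile(x, fs, w, p), tolerance = 1e-12)
  }
  expect_error(sliding_percentile_baseline(1:10, 100, 0.005, 10),
               "parameter error")
  expect_error(sliding_percentile_baseline(c(1, NA, 3), 100, 1, 10),
               "data error")
})

test_that("prenormalize computes (F - F0)/F0 and guards the divisor", {
  expect_equal(prenormalize(12, 10), 0.2)
  expect_equal(prenormalize(9, 10), -0.1)
  x <- runif(50, 5, 10)
  expect_equal(prenormalize(x, x), rep(0, 50))
  expect_error(prenormalize(c(1, 1), c(1, 0)), "numeric-guard error.*index 2")
})

test_that("reference low-pass is zero-phase with unit DC gain and the Butterworth response", {
  fs <- 1000
  x <- rep(3.7, 2000)
  expect_equal(lowpass_reference(x, fs), x, tolerance = 1e-6)
  # passband tone preserved, stopband attenuated per |H|^2 = 1/(1+(f/fc)^4)
  t <- seq(0, 40, by = 1 / fs)
  tone <- function(f) sin(2 * pi * f * t)
  fit_amp <- function(y, f) {
    mid <- seq(round(5 * fs), round(35 * fs))
    co <- coef(lm(y[mid] ~ sin(2 * pi * f * t[mid]) + cos(2 * pi * f * t[mid])))
    sqrt(sum(co[2:3]^2))
  }
  y01 <- lowpass_reference(tone(0.1), fs)
  expect_equal(fit_amp(y01, 0.1), 1, tolerance = 0.01)
  y30 <- lowpass_reference(tone(30), fs)
  expect_equal(fit_amp(y30, 30), 1 / (1 + (30 / 3)^4), tolerance = 0.02)
  expect_error(lowpass_reference(x, fs, corner_hz = 600), "parameter error")
})

test_that("RANSAC affine fit recovers exact and outlier-contaminated relations", {
  set.seed(1)
  ref <- runif(2000, 1, 3)
  sig <- 2 * ref + 1
  fit <- fit_reference(ref, sig)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_true(all(fit$inlier_mask))
  # OLS refit on the inlier set reproduces the fit
  ols <- lm(sig[fit$inlier_mask] ~ ref[fit$inlier_mask])
  expect_equal(unname(coef(ols)), c(fit$intercept, fit$slope),
               tolerance = 1e-9)

  corrupt <- sample.int(2000, 100)
  sig2 <- sig
  sig2[corrupt] <- sig2[corrupt] + sample(c(-100, 100), 100, replace = TRUE)
  fit2 <- fit_reference(ref, sig2)
  expect_equal(fit2$slope, 2, tolerance = 1e-3)
  expect_equal(fit2$intercept, 1, tolerance = 1e-3)
  expect_true(all(!fit2$inlier_mask[corrupt]))
  # deterministic given the seed
  fit3 <- fit_reference(ref, sig2)
  expect_identical(fit2$slope, fit3$slope)

  expect_error(fit_reference(rep(1, 100), rnorm(100)), "degenerate reference")
})

test_that("reference subtraction is the stated affine subtraction", {
  x <- rnorm(100)
  fit <- structure(list(slope = 1, intercept = 0), class = "ransac_fit")
  out <- reference_subtract(x, fit, numeric(100))
  expect_equal(out$dff, x)
  out2 <- reference_subtract(x, fit, x)
  expect_equal(out2$dff, rep(0, 100))
})

test_that("QC gate implements the inclusion rule on both thresholds", {
  f <- qc_fixture(2.0, 0.3)
  expect_true(qc_gate(f$dff, f$transformed)$passed)
  f <- qc_fixture(1.0, 0.3)
  expect_false(qc_gate(f$dff, f$transformed)$passed)
  f <- qc_fixture(5.0, 0.7)
  q <- qc_gate(f$dff, f$transformed)
  expect_false(q$passed)
  expect_gt(q$signal_reference_correlation, 0.6)
})

test_that("gcamp chain: null session, z-score contract, scale invariance, QC outcomes", {
  null_p <- sim_params(duration_s = 12,
                       bleach = list(signal = list(a1 = 0, tau1 = 1, a2 = 0, tau2 = 1),
                                     reference = list(a1 = 0, tau1 = 1, a2 = 0, tau2 = 1)),
                       artifact = list(rate_per_min = 0),
                       transient = list(rate_move = 0, rate_rest = 0),
                       noise = list(signal_sd = 0, reference_sd = 0))
  ns <- simulate_photometry(null_p, seed = 1)$session
  n0 <- normalize_gcamp(ns)
  expect_equal(n0$dff, numeric(length(ns$time)))
  expect_false(n0$qc$passed)

  p <- sim_params(duration_s = 30, coupling = list(profile = "patch_like"))
  loc <- simulate_locomotion(p, seed = 2)
  sess <- simulate_photometry(p, velocity = loc$velocity, seed = 3)$session
  norm <- normalize_gcamp(sess)
  expect_true(norm$qc$passed)
  expect_lt(abs(mean(norm$zscore)), 1e-9)
  expect_lt(abs(sd(norm$zscore) - 1), 1e-9)
  # common scaling of both raw channels leaves dF/F unchanged
  scaled <- photometry_session(3.5 * sess$signal, 3.5 * sess$reference,
                               sess$sampling_rate, "gcamp")
  norm_s <- normalize_gcamp(scaled)
  expect_equal(norm_s$dff, norm$dff, tolerance = 1e-9)

  art_p <- sim_params(duration_s = 30,
                      artifact = list(rate_per_min = 40, amp_mean = 6),
                      transient = list(rate_move = 0, rate_rest = 0),
                      coupling = list(profile = "none"))
  an <- normalize_gcamp(simulate_photometry(art_p, seed = 4)$session)
  expect_false(an$qc$passed)
  expect_gte(an$qc$signal_reference_correlation, 0.6)
})

test_that("rdam chain references raw channels and preserves stimulation offsets", {
  fs <- 1000
  t <- seq(0, 20, by = 1 / fs)
  ref <- 80 + 5 * exp(-t / 10)
  perfect <- photometry_session(3 * ref, ref, fs, "rdam", time = t)
  nr <- normalize_rdam(perfect)
  expect_equal(nr$dff, numeric(length(t)), tolerance = 1e-9)

  p <- sim_params(noise = list(signal_sd = 0.05, reference_sd = 0.05),
                  artifact = list(rate_per_min = 0),
                  stim = list(durations_s = 15, trials_per_duration = 2,
                              depth = -0.5))
  sim <- simulate_stim_session(p, seed = 5)
  nd <- normalize_rdam(sim$session)
  ev <- sim$session$events[[1]]
  during <- nd$time >= ev$onsets[1] + 5 & nd$time < ev$offsets[1]
  expect_equal(mean(nd$dff[during]), -0.5, tolerance = 0.02)

  expect_error(normalize_rdam(tiny_session(sensor_kind = "gcamp")),
               "precondition error")
  expect_error(normalize_gcamp(tiny_session(sensor_kind = "rdam")),
               "precondition error")
})
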