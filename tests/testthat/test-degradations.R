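test_that("additive noise hits the requested SNR analytically", {
  set.seed(5)
  sig <- calibrate_level(audio_signal(rnorm(6000), 16000), 65)
  # clean passthrough
  expect_identical(add_noise_at_snr(sig, Inf)$samples, sig$samples)
  # 0 dB: noise RMS equals signal RMS by construction
  parts <- add_noise_at_snr(sig, 0, rng_seed = 2, return_components = TRUE)
  expect_equal(signal_rms(parts$noise), signal_rms(sig), tolerance = 1e-9)
  # measured SNR of the stored components recovers the request
  for (snr in c(12, 0, -7.3, -18)) {
    p <- add_noise_at_snr(sig, snr, rng_seed = 31, return_components = TRUE)
    measured <- 10 * log10(mean(p$signal$samples^2) / mean(p$noise$samples^2))
    expect_equal(measured, snr, tolerance = 1e-6)
    expect_equal(p$mixture$samples, p$signal$samples + p$noise$samples)
  }
  # determinism and argument validation
  expect_identical(add_noise_at_snr(sig, -6, rng_seed = 7)$samples,
                   add_noise_at_snr(sig, -6, rng_seed = 7)$samples)
  expect_error(add_noise_at_snr(sig, NaN), "non-missing")
})

test_that("reverberation is full linear convolution with level re-calibration", {
  set.seed(6)
  sig <- calibrate_level(audio_signal(rnorm(800), 8000), 65)
  # unit impulse: identity up to level re-calibration
  unit <- impulse_response(c(1), 8000)
  out <- apply_reverb(sig, unit)
  expect_equal(out$samples[seq_along(sig$samples)], sig$samples, tolerance = 1e-9)
  # delayed impulse: pure shift
  del <- impulse_response(c(0, 0, 0, 1), 8000)
  outd <- apply_reverb(sig, del)
  expect_equal(length(outd$samples), length(sig$samples) + 3)
  # shifted copy up to the level re-calibration gain (the padded output is
  # longer, so its re-calibration gain differs slightly)
  shifted <- outd$samples[4:(3 + length(sig$samples))]
  expect_equal(shifted / signal_rms(shifted), sig$samples / signal_rms(sig),
               tolerance = 1e-9)
  expect_equal(outd$samples[1:3], rep(0, 3), tolerance = 1e-12)
  # two-tap IR against hand convolution (shapes proportional; output is
  # re-calibrated to the presentation level)
  x <- audio_signal(c(1, 2, 3), 8000, level_db_spl = 65)
  h <- impulse_response(c(1, 0.5), 8000)
  y <- apply_reverb(x, h)
  manual <- c(1, 2.5, 4, 1.5)
  expect_equal(y$samples / y$samples[1], manual / manual[1], tolerance = 1e-9)
  expect_equal(signal_rms(y), SPL_REFERENCE * 10^(65 / 20), tolerance = 1e-9)
  # linearity up to re-calibration: scaling the input leaves the output
  # identical (both re-calibrated to the same level)
  y2 <- apply_reverb(audio_signal(3 * sig$samples, 8000, level_db_spl = 65), del)
  expect_equal(y2$samples, outd$samples, tolerance = 1e-9)
  expect_error(apply_reverb(sig, impulse_response(numeric(0), 8000)))
})

test_that("T30 estimation matches the analytic decay and is scale invariant", {
  fs <- 16000
  # deterministic exponential energy decay at -60 dB/s: T30 = 500 ms
  t <- (0:(1.5 * fs)) / fs
  ir <- impulse_response(10^(-1.5 * t), fs)
  est <- estimate_t30(ir)
  expect_equal(as.numeric(est), 500, tolerance = 0.01 * 500)
  # amplitude scale invariance
  ir2 <- impulse_response(7 * ir$samples, fs)
  expect_equal(as.numeric(estimate_t30(ir2)), as.numeric(est), tolerance = 1e-9)
  # single-sample impulse: below one sample period
  expect_lt(as.numeric(estimate_t30(impulse_response(1, fs))), 1000 / fs + 1e-9)
  # decay that never reaches -30 dB is flagged as an upper bound
  flat <- impulse_response(rep(1, 100), fs)
  expect_warning(ub <- estimate_t30(flat), "upper bound")
  expect_true(attr(ub, "censored"))
})

test_that("synthetic impulse responses round-trip through the T30 estimator", {
  for (target in c(7, 128, 644)) {
    ir <- synth_impulse_response(target, sample_rate = 16000, rng_seed = 12)
    expect_equal(ir$t30_ms, target)
    est <- as.numeric(estimate_t30(ir))
    expect_lt(abs(est - target) / target, 0.10)
  }
  # determinism
  a <- synth_impulse_response(100, rng_seed = 3)
  b <- synth_impulse_response(100, rng_seed = 3)
  expect_identical(a$samples, b$samples)
  expect_error(synth_impulse_response(100, duration_ms = 150), "at least")
})
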