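test_that("call synthesis is reproducible and calibrated", {
  spec <- call_class_spec("tone", "tonal", c(1000, 1200), c(200, 300),
                          harmonics = 2, jitter = 0)
  a <- synth_call(spec, rng_seed = 5)
  b <- synth_call(spec, rng_seed = 5)
  expect_identical(a$samples, b$samples)
  expect_equal(signal_rms(a), SPL_REFERENCE * 10^(65 / 20), tolerance = 1e-9)
  expect_equal(attr(a, "label"), "tone")
})

test_that("frequency sweeps rise monotonically along the cochleagram ridge", {
  spec <- call_class_spec("sweep", "fm_sweep", c(500, 500), c(300, 300),
                          harmonics = 1, sweep_rate_range_oct = c(3, 3),
                          jitter = 0)
  x <- synth_call(spec, rng_seed = 2)
  g <- make_cf_grid(300, 4800, 0.1)
  cc <- compute_cochleagram(x, g)
  active <- which(apply(cc$values, 1, max) > 0.5 * max(cc$values))
  ridge <- apply(cc$values[active, ], 1, which.max)
  steps <- diff(ridge)
  expect_gt(mean(steps >= 0), 0.9)           # essentially non-decreasing
  expect_gt(ridge[length(ridge)], ridge[1])  # net rise
})

test_that("amplitude-modulated noise carries its AM rate in the envelope spectrum", {
  spec <- call_class_spec("am", "am_noise", c(300, 300), c(500, 500),
                          am_rate_range_hz = c(12, 12), band_oct = 1.5,
                          jitter = 0)
  x <- synth_call(spec, rng_seed = 8)
  g <- make_cf_grid(250, 1400, 0.1)
  cc <- compute_cochleagram(x, g)
  env <- rowMeans(cc$values)
  env <- env - mean(env)
  sp <- Mod(stats::fft(env))^2
  freqs <- (seq_along(sp) - 1) * cc$frame_rate / length(sp)
  band <- freqs > 3 & freqs < 50
  expect_lt(abs(freqs[band][which.max(sp[band])] - 12), 2.5)
})

test_that("corpora are balanced, reproducible and split disjointly", {
  specs <- default_call_classes()
  corp1 <- make_corpus(specs, n_per_class = 1, rng_seed = 3)
  expect_length(corp1$calls, 4)
  expect_setequal(corp1$labels, c("chut", "wheek", "rumble", "whine"))
  corp2 <- make_corpus(specs, n_per_class = 1, rng_seed = 3)
  expect_identical(lapply(corp2$calls, `[[`, "samples"),
                   lapply(corp1$calls, `[[`, "samples"))
  corp <- make_corpus(specs, n_per_class = 6, rng_seed = 5)
  sp <- split_corpus(corp, 0.5, rng_seed = 9)
  expect_equal(length(sp$train$calls) + length(sp$test$calls), 24)
  expect_equal(as.integer(table(sp$train$labels)), rep(3L, 4))
})

test_that("the default classes are separable in their long-term spectra", {
  cs <- tiny_labeled_cochs()
  spectra <- t(vapply(cs$cochleagrams, function(cc) {
    v <- colMeans(cc$values)
    v / sqrt(sum(v^2))
  }, numeric(ncol(cs$cochleagrams[[1]]$values))))
  centroids <- rowsum(spectra, cs$labels) / as.integer(table(cs$labels))
  between <- sqrt(sum((centroids[1, ] - centroids[2, ])^2))
  within <- mean(vapply(seq_len(nrow(spectra)), function(i)
    sqrt(sum((spectra[i, ] - centroids[cs$labels[i], ])^2)), numeric(1)))
  expect_gt(between, within)
})
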