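test_that("CF grids are log-spaced and match brute-force enumeration", {
  expect_equal(make_cf_grid(200, 400, 1)$frequencies, c(200, 400))
  expect_equal(make_cf_grid(1000, 1000, 0.1)$frequencies, 1000)
  # brute-force enumeration oracle over assorted parameters
  brute <- function(f_min, f_max, step) {
    out <- c(); f <- f_min; k <- 0
    while (f <= f_max * (1 + 1e-12)) {
      out <- c(out, f); k <- k + 1; f <- f_min * 2^(k * step)
    }
    out
  }
  cases <- list(c(200, 20000, 0.1), c(150, 7000, 0.25), c(100, 101, 0.001),
                c(500, 12345, 0.33))
  for (cs in cases) {
    g <- make_cf_grid(cs[1], cs[2], cs[3])
    expect_equal(g$frequencies, brute(cs[1], cs[2], cs[3]), tolerance = 1e-9)
    # consecutive ratio invariant
    if (length(g$frequencies) > 1)
      expect_equal(diff(log2(g$frequencies)), rep(cs[3], length(g$frequencies) - 1),
                   tolerance = 1e-9)
  }
  expect_error(make_cf_grid(-1, 100, 0.1), "positive")
  expect_error(make_cf_grid(100, 200, 0), "positive")
})

test_that("an on-CF tone dominates its own channel and silence maps to zero", {
  g <- make_cf_grid(400, 3200, 0.1)
  fs <- 16000
  tt <- (0:7999) / fs
  j <- 11
  tone <- calibrate_level(audio_signal(sin(2 * pi * g$frequencies[j] * tt), fs), 65)
  cc <- compute_cochleagram(tone, g)
  peaks <- apply(cc$values, 2, max)
  expect_equal(which.max(peaks), j)
  expect_true(all(cc$values >= 0))
  # a tone 0.3 octaves above channel j activates the nearest channel more
  f_off <- g$frequencies[j] * 2^0.3
  tone2 <- calibrate_level(audio_signal(sin(2 * pi * f_off * tt), fs), 65)
  cc2 <- compute_cochleagram(tone2, g)
  nearest <- which.min(abs(log2(g$frequencies / f_off)))
  expect_gt(max(cc2$values[, nearest]), max(cc2$values[, j]))
  # silence
  sil <- audio_signal(rep(0, 4000), fs)
  expect_true(all(compute_cochleagram(sil, g)$values == 0))
  # too-short input
  expect_error(compute_cochleagram(audio_signal(rnorm(5), fs), g), "shorter")
})

test_that("the cochleagram is time-shift equivariant and gain monotone", {
  g <- make_cf_grid(400, 3200, 0.1)
  fs <- 16000
  set.seed(11)
  burst <- c(rep(0, 1600), rnorm(3200) * seq(1, 2, length.out = 3200), rep(0, 1600))
  x1 <- audio_signal(burst, fs)
  k_ms <- 15
  x2 <- audio_signal(c(rep(0, k_ms * 16), burst), fs)
  c1 <- compute_cochleagram(x1, g)
  c2 <- compute_cochleagram(x2, g)
  interior <- 60:(nrow(c1$values) - 60)
  expect_equal(c2$values[interior + k_ms, ], c1$values[interior, ],
               tolerance = 1e-6)
  # scaling the waveform up never decreases any activation
  c3 <- compute_cochleagram(audio_signal(2 * burst, fs), g)
  expect_true(all(c3$values >= c1$values - 1e-12))
})

test_that("cochleagrams round-trip through the on-disk layout", {
  cc <- rand_coch(20, 8, seed = 4)
  path <- tempfile()
  write_cochleagram(cc, path)
  back <- read_cochleagram(path)
  expect_equal(back$values, cc$values, tolerance = 1e-12)
  expect_equal(back$frame_rate, cc$frame_rate)
  expect_equal(back$grid$frequencies, cc$grid$frequencies, tolerance = 1e-9)
  unlink(paste0(path, c(".csv", ".json")))
})
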