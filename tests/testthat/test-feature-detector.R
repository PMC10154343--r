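test_that("core-mode responses equal the naive sliding-window oracle", {
  for (seed in 1:5) {
    cc <- rand_coch(50, 14, seed = seed)
    set.seed(seed + 100)
    fd <- feature_detector(matrix(rnorm(8 * 5), 8, 5), c(3, 7))
    vm <- vm_response(fd, cc, "core")
    block <- cc$values[, 3:7]
    expect_equal(vm$values, oracle_vm_core(fd$strf, block), tolerance = 1e-9)
  }
})

test_that("local gain control yields bounded correlations with unit autocorrelation peak", {
  cc <- rand_coch(80, 16, seed = 3)
  # a patch of the cochleagram matched against its own source
  patch <- cc$values[21:40, 5:10]
  fd <- feature_detector(patch, c(5, 10))
  vm <- vm_response(fd, cc, "cgc_local")
  expect_true(all(vm$values >= -1 & vm$values <= 1))
  expect_equal(max(vm$values), 1, tolerance = 1e-12)
  expect_equal(which.max(vm$values), 21)
  # constant cochleagram: every window degenerate, all values 0 and flagged
  const <- as_cochleagram(matrix(2, 40, 16))
  vm0 <- vm_response(fd, const, "cgc_local")
  expect_true(all(vm0$values == 0))
  expect_equal(vm0$n_degenerate, length(vm0$values))
  # zero-variance input is a hard error in global mode
  expect_error(vm_response(fd, const, "cgc_global"), "degenerate")
})

test_that("gain-control modes are affine invariant while core mode is not", {
  cc <- rand_coch(60, 12, seed = 7)
  set.seed(8)
  fd <- feature_detector(matrix(rnorm(10 * 4), 10, 4), c(4, 7))
  shifted <- as_cochleagram(3.7 * cc$values + 1.9, cc$frame_rate, cc$grid)
  for (mode in c("cgc_local", "cgc_global")) {
    expect_equal(vm_response(fd, shifted, mode)$values,
                 vm_response(fd, cc, mode)$values, tolerance = 1e-9)
  }
  core1 <- vm_response(fd, cc, "core")$values
  core2 <- vm_response(fd, shifted, "core")$values
  expect_gt(max(abs(core2 - core1)), 1e-6)
})

test_that("detection applies the scaled threshold with an inclusive boundary", {
  cc <- rand_coch(40, 10, seed = 2)
  fd <- feature_detector(cc$values[5:12, 3:6], c(3, 6))
  vm_max <- max(vm_response(fd, cc, "core")$values)
  fd$threshold <- vm_max                    # boundary: exactly at threshold
  expect_equal(fd_detect(fd, cc, "core", kappa = 1), 1L)
  expect_equal(fd_detect(fd, cc, "core", kappa = 1e-6), 1L)  # kappa -> 0+
  expect_equal(fd_detect(fd, cc, "core", kappa = 1e6), 0L)   # kappa -> Inf
  # scaling cochleagram and threshold together leaves core detection fixed
  fd2 <- fd; fd2$threshold <- fd$threshold * 5
  cc5 <- as_cochleagram(5 * cc$values, cc$frame_rate, cc$grid)
  expect_equal(fd_detect(fd2, cc5, "core"), fd_detect(fd, cc, "core"))
  expect_error(fd_detect(fd, cc, "core", kappa = -1), "positive")
})

test_that("detector properties follow their definitions", {
  g <- make_cf_grid(1000, 4000, 2)      # 1000, 4000 Hz: a 2-octave span
  # hand-checkable moments on a printed matrix
  m <- matrix(c(1, 2, 3, 4, 5, 9), 3, 2)
  fd <- feature_detector(m, c(1, 2), frame_rate = 1000, threshold = 0.5)
  p <- fd_properties(fd, g)
  expect_equal(p$duration_ms, 3)
  expect_equal(p$center_frequency_hz, sqrt(1000 * 4000))
  expect_equal(p$bandwidth_oct, 2)
  v <- as.numeric(m); mu <- mean(v); sdv <- sqrt(mean((v - mu)^2))
  expect_equal(p$reduced_kurtosis, mean((v - mu)^4) / sdv^4 - 3, tolerance = 1e-12)
  # Gaussian entries: excess kurtosis near zero
  set.seed(1)
  big <- feature_detector(matrix(rnorm(100 * 100), 100, 100), c(1, 100))
  g2 <- make_cf_grid(200, 200 * 2^(99 * 0.1), 0.1)
  expect_lt(abs(fd_properties(big, g2)$reduced_kurtosis), 0.2)
  # degenerate patch flagged
  flat <- feature_detector(matrix(1, 2, 2), c(1, 2), threshold = 0)
  expect_warning(pf <- fd_properties(flat, make_cf_grid(200, 400, 0.1)),
                 "undefined")
  expect_true(is.na(pf$reduced_kurtosis))
})
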