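test_that("voting scores combine weighted detections as defined", {
  cc <- rand_coch(60, 10, seed = 21)
  m <- build_toy_model(cc, weights = c(1, 2, 3), fire = c(TRUE, FALSE, TRUE))
  vs <- voting_score(m, cc)
  expect_equal(vs$detections, c(1L, 0L, 1L))
  expect_equal(vs$raw, 4)
  expect_equal(vs$normalized, 4 / 6)
  all_on <- build_toy_model(cc, c(1, 2, 3), fire = rep(TRUE, 3))
  expect_equal(voting_score(all_on, cc)$normalized, 1)
  none <- build_toy_model(cc, c(1, 2, 3), fire = rep(FALSE, 3))
  vs0 <- voting_score(none, cc)
  expect_equal(vs0$raw, 0)
  expect_equal(vs0$normalized, 0)
})

test_that("rank-based AUC equals brute-force pairwise counting", {
  expect_equal(auc_from_scores(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auc_from_scores(c(4, 5), c(1, 2)), 1)
  for (i in 1:25) {
    set.seed(i)
    w <- sample(0:5, sample(2:9, 1), replace = TRUE) / 5
    o <- sample(0:5, sample(2:9, 1), replace = TRUE) / 5
    expect_identical(auc_from_scores(w, o), oracle_auc(w, o))
  }
  # invariant under strictly increasing score transforms
  set.seed(99)
  w <- runif(12); o <- runif(15)
  expect_equal(auc_from_scores(exp(w), exp(o)), auc_from_scores(w, o))
})

test_that("d-prime follows the probit mapping with symmetric clipping", {
  expect_equal(dprime_from_auc(0.5), 0)
  expect_equal(dprime_from_auc(0.75), -dprime_from_auc(0.25), tolerance = 1e-12)
  # cross-check the probit against an independent numerical inversion
  target <- 0.75
  inv <- stats::uniroot(function(z) stats::pnorm(z) - target, c(-10, 10),
                        tol = 1e-12)$root
  expect_equal(dprime_from_auc(0.75), sqrt(2) * inv, tolerance = 1e-8)
  # degenerate AUC clipped by the pair-count resolution
  expect_equal(dprime_from_auc(1, n_pairs = 50),
               sqrt(2) * stats::qnorm(1 - 1 / 100))
})

test_that("winner-take-all output is a bounded antisymmetric difference", {
  cc <- rand_coch(60, 10, seed = 5)
  target <- build_toy_model(cc, c(1, 1), fire = c(TRUE, TRUE))
  distract <- build_toy_model(cc, c(2, 3), fire = c(FALSE, FALSE))
  w <- wta_response(target, distract, cc)
  expect_equal(w$value, 1)     # all target features, no distractor features
  expect_equal(w$decision, "go")
  # no detections at all: value 0, strict rule gives no-go
  none <- build_toy_model(cc, c(1, 1), fire = c(FALSE, FALSE))
  w0 <- wta_response(none, distract, cc)
  expect_equal(w0$value, 0)
  expect_equal(w0$decision, "no-go")
  # antisymmetry and the hand example
  part <- build_toy_model(cc, c(3, 2), fire = c(TRUE, FALSE))
  ab <- wta_response(part, target, cc)
  ba <- wta_response(target, part, cc)
  expect_equal(ab$value, -ba$value)
  expect_equal(ab$value, 3 / 5 - 1)
  expect_true(all(abs(c(ab$value, ba$value)) <= 1))
})

test_that("the logistic behavior map is symmetric and recovers planted parameters", {
  expect_equal(logistic_go_rate(0, k = 3, lambda = 0.2), 0.5)
  expect_equal(logistic_go_rate(0, k = 50, lambda = 0.01), 0.5)
  # lambda = 0, large k approaches the ideal observer
  x <- c(-0.4, -0.01, 0.01, 0.5)
  expect_equal(logistic_go_rate(x, k = 1e4, lambda = 0), c(0, 0, 1, 1),
               tolerance = 1e-12)
  set.seed(14)
  wt <- pmin(pmax(rnorm(300, 0.35, 0.25), -1), 1)
  wd <- pmin(pmax(rnorm(300, -0.25, 0.25), -1), 1)
  k0 <- 4.5; l0 <- 0.12
  hit0 <- mean(logistic_go_rate(wt, k0, l0))
  fa0 <- mean(logistic_go_rate(wd, k0, l0))
  # curve matching identifies and recovers the planted pair
  fit <- fit_behavior_map(wt, wd,
                          target_go_rates = logistic_go_rate(c(wt, wd), k0, l0))
  expect_lt(abs(fit$k - k0) / k0, 0.01)
  expect_lt(abs(fit$lambda - l0), 0.005)
  # rate matching reproduces the behavioral hit/false-alarm rates (the
  # parameters themselves trade off along a ridge and are not asserted)
  fitr <- fit_behavior_map(wt, wd, target_hit = hit0, target_fa = fa0)
  expect_lt(abs(mean(logistic_go_rate(wt, fitr$k, fitr$lambda)) - hit0), 1e-4)
  expect_lt(abs(mean(logistic_go_rate(wd, fitr$k, fitr$lambda)) - fa0), 1e-4)
  # d-prime objective reproduces the behavioral d-prime it was given
  d0 <- stats::qnorm(hit0) - stats::qnorm(fa0)
  fit2 <- fit_behavior_map(wt, wd, target_dprime = d0)
  expect_lt(abs(fit2$achieved_dprime - d0), 0.02)
  # bounded behavioral d-prime given the floor/ceiling
  expect_lt(abs(fit2$achieved_dprime), 2 * abs(stats::qnorm(1 - fit2$lambda)) + 1e-9)
  # unattainable target returns the boundary with a warning
  expect_warning(fit_behavior_map(wt, wd, target_dprime = 12), "boundary")
})
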