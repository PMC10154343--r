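test_that("MI-optimal thresholds match the exhaustive scan on random instances", {
  # perfect balanced separation: MI = H(class) = 1 bit, largest tie wins
  fit <- learn_threshold(rep(5, 10), rep(1, 10))
  expect_equal(fit$threshold, 5)
  expect_equal(fit$mi_bits, 1)
  # identically distributed classes carry no information
  set.seed(4)
  v <- rnorm(30)
  expect_lt(learn_threshold(v, v)$mi_bits, 1e-12)
  # interleaved example against the independent exhaustive oracle
  fit2 <- learn_threshold(c(1, 3, 5), c(2, 4, 6))
  or2 <- oracle_threshold(c(1, 3, 5), c(2, 4, 6))
  expect_equal(fit2$threshold, or2$threshold)
  expect_equal(fit2$mi_bits, or2$mi_bits, tolerance = 1e-12)
  # property: equality on many random small instances
  for (i in 1:60) {
    set.seed(i)
    w <- round(rnorm(sample(3:12, 1)), 1)
    o <- round(rnorm(sample(3:12, 1), mean = runif(1, -1, 1)), 1)
    fit <- learn_threshold(w, o)
    or <- oracle_threshold(w, o)
    expect_equal(fit$mi_bits, or$mi_bits, tolerance = 1e-12)
    expect_equal(fit$threshold, or$threshold)
  }
})

test_that("threshold MI is invariant to joint monotone transforms of the maxima", {
  set.seed(12)
  w <- rnorm(20, 1); o <- rnorm(25)
  base <- learn_threshold(w, o)
  for (f in list(function(x) exp(x), function(x) x^3, function(x) 2 * x - 5)) {
    tr <- learn_threshold(f(w), f(o))
    expect_equal(tr$mi_bits, base$mi_bits, tolerance = 1e-12)
    expect_equal(tr$threshold, f(base$threshold), tolerance = 1e-9)
  }
})

test_that("log-likelihood weights follow the smoothed formula", {
  expect_equal(learn_weight(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  # all within detected, none outside, n = 10 each
  expect_equal(learn_weight(rep(1, 10), rep(0, 10)),
               log2(11 / 12) - log2(1 / 12))
  # antisymmetry under class swap
  set.seed(2)
  a <- rbinom(15, 1, 0.7); b <- rbinom(12, 1, 0.2)
  expect_equal(learn_weight(a, b), -learn_weight(b, a))
})

test_that("candidate sampling is seeded, bounded and uniform in duration", {
  cs <- tiny_labeled_cochs()
  corpus <- training_corpus(cs$cochleagrams, cs$labels, "wheek")
  p1 <- sample_candidates(corpus, 30, rng_seed = 6)
  p2 <- sample_candidates(corpus, 30, rng_seed = 6)
  expect_identical(lapply(p1$candidates, `[[`, "strf"),
                   lapply(p2$candidates, `[[`, "strf"))
  # degenerate bounds force the whole cochleagram
  nt <- nrow(corpus$within[[1]]$values)
  nc <- ncol(corpus$within[[1]]$values)
  step <- corpus$within[[1]]$grid$step_octaves
  # wheek durations vary; force the shortest one exactly
  nts <- vapply(corpus$within, function(x) nrow(x$values), integer(1))
  full_ms <- min(nts)                       # frames == ms at 1 kHz
  pf <- sample_candidates(corpus, 3,
                          size_bounds = list(duration_ms = c(full_ms, full_ms),
                                             bandwidth_oct = c((nc - 1) * step,
                                                               (nc - 1) * step)),
                          rng_seed = 2)
  for (cand in pf$candidates) {
    expect_equal(ncol(cand$strf), nc)
    expect_equal(nrow(cand$strf), full_ms)
  }
  # infeasible bounds error out
  expect_error(sample_candidates(corpus, 2,
                                 size_bounds = list(duration_ms = c(5000, 6000),
                                                    bandwidth_oct = c(0.5, 1))),
               "could not sample")
  # duration distribution approximately uniform within the bounds
  pu <- sample_candidates(corpus, 1500,
                          size_bounds = list(duration_ms = c(60, 200),
                                             bandwidth_oct = c(0.5, 2)),
                          rng_seed = 10)
  durs <- vapply(pu$candidates, function(f) f$duration_ms, numeric(1))
  ecdf_mid <- mean(durs <= 130)
  expect_lt(abs(ecdf_mid - 0.5), 0.05)
  expect_lt(abs(mean(durs <= 95) - 0.25), 0.05)
})

test_that("greedy search selects a dominating set and respects its contract", {
  # constructed detection patterns: A covers w1-w2, B covers w3-w4, C is
  # individually strongest but redundant with A and causes a false alarm
  det <- rbind(
    A = c(1, 1, 0, 0, 0, 0, 0, 0),
    B = c(0, 0, 1, 1, 0, 0, 0, 0),
    C = c(1, 1, 1, 0, 1, 0, 0, 0),
    D = c(0, 0, 0, 0, 1, 1, 0, 0))   # anti-informative
  nw <- 4; no <- 4
  mi <- apply(det, 1, function(d) {
    fit <- oracle_threshold(d[1:nw] + 0, d[-(1:nw)] + 0)
    fit$mi_bits
  })
  weight <- apply(det, 1, function(d) learn_weight(d[1:nw], d[-(1:nw)]))
  stats <- list(vmmax = det, threshold = rep(0.5, 4), mi = mi,
                weight = weight, det = det == 1, n_within = nw, n_outside = no)
  cc <- rand_coch(30, 10, seed = 1)
  corpus <- training_corpus(list(cc, cc, cc, cc, cc, cc, cc, cc),
                            c(rep("x", 4), rep("y", 4)), "x")
  fds <- lapply(rownames(det), function(id) {
    fd <- feature_detector(matrix(rnorm(4), 2, 2), c(1, 2))
    fd$id <- id
    fd
  })
  pool <- structure(list(candidates = fds, rng_seed = 1L),
                    class = "candidate_pool")
  model <- greedy_mif_search(pool, corpus, stats = stats)
  picked <- vapply(model$fds, `[[`, character(1), "id")
  expect_setequal(picked, c("A", "B"))
  final <- model$trajectory[nrow(model$trajectory), ]
  expect_equal(final$hit, 1)
  expect_equal(final$fa, 0)
  # exhaustive enumeration: no same-size subset beats (hit = 1, fa = 0)
  combos <- utils::combn(4, 2)
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    votes_w <- colSums(weight[idx] * det[idx, 1:nw, drop = FALSE])
    votes_o <- colSums(weight[idx] * det[idx, -(1:nw), drop = FALSE])
    expect_false(mean(votes_w > 0) > final$hit && mean(votes_o > 0) < final$fa)
  }
  # trajectory is monotone by construction
  expect_true(all(diff(model$trajectory$hit) > 0))
  expect_true(all(diff(model$trajectory$fa) <= 0))
})

test_that("fitting one call type yields a working model with clean methods", {
  cs <- tiny_labeled_cochs()
  corpus <- training_corpus(cs$cochleagrams, cs$labels, "chut")
  m <- mif_train(corpus, n_candidates = 30, rng_seed = 3)
  expect_s3_class(m, "mif_model")
  expect_lte(length(m$fds), 20)
  expect_gt(length(m$fds), 0)
  p <- predict(m, cs$cochleagrams)
  expect_true(all(p$normalized >= 0 & p$normalized <= 1))
  expect_gt(mean(p$normalized[cs$labels == "chut"]),
            mean(p$normalized[cs$labels == "wheek"]))
  ct <- coef(m)
  expect_equal(nrow(ct), length(m$fds))
  expect_true(all(ct$weight > 0))
  expect_output(print(summary(m)), "MIF model")
  # serialization round-trip preserves predictions
  f <- tempfile(fileext = ".json")
  write_mif_model(m, f)
  m2 <- read_mif_model(f)
  expect_equal(predict(m2, cs$cochleagrams), p)
  unlink(f)
})

test_that("ensemble instantiations are non-overlapping and reduce to one search", {
  cs <- tiny_labeled_cochs()
  corpus <- training_corpus(cs$cochleagrams, cs$labels, "wheek")
  ens <- mif_train_ensemble(corpus, k = 3, n_candidates = 40, rng_seed = 5)
  ids <- lapply(ens$models, function(m) vapply(m$fds, `[[`, character(1), "id"))
  for (i in seq_along(ids))
    for (j in seq_len(i - 1))
      expect_length(intersect(ids[[i]], ids[[j]]), 0)
  # k = 1 equals a single greedy search on the same pool
  one <- mif_train_ensemble(corpus, k = 1, n_candidates = 40, rng_seed = 5)
  single <- mif_train(corpus, n_candidates = 40, rng_seed = 5)
  expect_identical(vapply(one$models[[1]]$fds, `[[`, character(1), "id"),
                   vapply(single$fds, `[[`, character(1), "id"))
})
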