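#' Configuration of the experiment matrix
#'
#' Bundles every knob of the end-to-end study: the synthetic call classes,
#' corpus and split sizes, the analysis grid and front-end, the noise and
#' reverberation test grids, the training conditions, the mechanisms to
#' compare, and the training scale.  The defaults define the package's
#' reference study; `run_experiment_matrix()` consumes the object.
#'
#' Mechanisms combine a matching mode with a top-down kappa policy:
#' `"core"` (plain matching, kappa = 1), `"cgc"` (local contrast gain
#' control), `"cgc_global"` (global cochleagram normalization),
#' `"topdown"` (core matching, per-condition MI-optimal kappa),
#' `"topdown_proxy"` (core matching, per-stimulus kappa from the fitted
#' mu/sigma map), `"cgc_topdown"` (local gain control plus oracle kappa).
#'
#' @param classes named list of [call_class_spec()].
#' @param n_per_class calls generated per class.
#' @param train_frac fraction of each class used for training.
#' @param sample_rate waveform sampling rate, Hz.
#' @param grid analysis [make_cf_grid()].
#' @param frontend [frontend_config()].
#' @param snr_grid_db test SNRs in dB (`Inf` = clean).
#' @param t30_grid_ms test reverberation strengths (T30, ms); the default
#'   spans naturalistic (7 ms) through strongly reverberant (644 ms) rooms.
#' @param train_conditions subset of `c("clean", "noise", "reverb",
#'   "mixed")`.
#' @param mechanisms subset of the mechanism names above.
#' @param n_candidates candidate features sampled per call type.
#' @param instantiations non-overlapping model instantiations per call type.
#' @param max_set MIF-set size cap.
#' @param size_bounds candidate size bounds.
#' @param kappa_grid top-down threshold-ratio grid.
#' @param n_tune_per_class training calls per class reserved (re-used
#'   degraded) for tuning kappa.
#' @param keep_clean_in_training whether degraded-condition training keeps
#'   the clean calls alongside the degraded copies.
#' @param seed master seed; every random stage derives its own sub-seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(classes = default_call_classes(),
                              n_per_class = 100,
                              train_frac = 0.5,
                              sample_rate = 16000,
                              grid = make_cf_grid(200, 6400, 0.1),
                              frontend = frontend_config(),
                              snr_grid_db = c(-18, -12, -6, 0, 6, 12, Inf),
                              t30_grid_ms = c(7, 57, 81, 124, 128, 236, 461, 644),
                              train_conditions = "clean",
                              mechanisms = c("core", "cgc", "topdown"),
                              n_candidates = 200,
                              instantiations = 5,
                              max_set = 20,
                              size_bounds = list(duration_ms = c(50, 250),
                                                 bandwidth_oct = c(0.5, 3)),
                              kappa_grid = seq(0.25, 1.2, by = 0.01),
                              n_tune_per_class = 15,
                              keep_clean_in_training = TRUE,
                              seed = 1L) {
  train_conditions <- match.arg(train_conditions,
                                c("clean", "noise", "reverb", "mixed"),
                                several.ok = TRUE)
  mechanisms <- match.arg(mechanisms,
                          c("core", "cgc", "cgc_global", "topdown",
                            "topdown_proxy", "cgc_topdown"),
                          several.ok = TRUE)
  assert_that(length(snr_grid_db) + length(t30_grid_ms) > 0, "empty test grids")
  structure(list(classes = classes, n_per_class = n_per_class,
                 train_frac = train_frac, sample_rate = sample_rate,
                 grid = grid, frontend = frontend,
                 snr_grid_db = snr_grid_db, t30_grid_ms = t30_grid_ms,
                 train_conditions = train_conditions, mechanisms = mechanisms,
                 n_candidates = n_candidates, instantiations = instantiations,
                 max_set = max_set, size_bounds = size_bounds,
                 kappa_grid = kappa_grid, n_tune_per_class = n_tune_per_class,
                 keep_clean_in_training = keep_clean_in_training,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

mechanism_mode <- function(mech) {
  switch(mech,
         core = "core", topdown = "core", topdown_proxy = "core",
         cgc = "cgc_local", cgc_topdown = "cgc_local",
         cgc_global = "cgc_global")
}

mechanism_policy <- function(mech) {
  switch(mech,
         core = "off", cgc = "off", cgc_global = "off",
         topdown = "oracle", cgc_topdown = "oracle",
         topdown_proxy = "proxy")
}

# condition table: one row per test condition
condition_table <- function(config) {
  rows <- list()
  for (snr in sort(config$snr_grid_db, decreasing = TRUE)) {
    rows[[length(rows) + 1L]] <- data.frame(
      condition = if (is.infinite(snr)) "clean" else sprintf("snr_%+d_dB", snr),
      test_type = if (is.infinite(snr)) "clean" else "noise",
      snr_db = snr, t30_ms = NA_real_)
  }
  for (t30 in config$t30_grid_ms) {
    rows[[length(rows) + 1L]] <- data.frame(
      condition = sprintf("t30_%d_ms", round(t30)), test_type = "reverb",
      snr_db = NA_real_, t30_ms = t30)
  }
  do.call(rbind, rows)
}

# degrade a corpus for one condition row
degrade_for_condition <- function(corpus, cond, irs, seed) {
  if (cond$test_type == "reverb")
    degrade_corpus(corpus, ir = irs[[cond$condition]])
  else
    degrade_corpus(corpus, snr_db = cond$snr_db, rng_seed = seed)
}

# training cochleagram set for one training condition
build_training_set <- function(train_corpus, condition, config, irs, seed) {
  clean <- corpus_cochleagrams(train_corpus, config$grid, config$frontend)
  if (condition == "clean") return(clean)
  n <- length(train_corpus$calls)
  set.seed(derive_seed(seed, 71))
  finite_snrs <- config$snr_grid_db[is.finite(config$snr_grid_db)]
  ir_names <- names(irs)
  pick_noise <- sample(finite_snrs, n, replace = TRUE)
  pick_ir <- sample(ir_names, n, replace = TRUE)
  use_reverb <- switch(condition,
                       noise = rep(FALSE, n),
                       reverb = rep(TRUE, n),
                       mixed = seq_len(n) %% 2 == 0)
  calls <- vector("list", n)
  for (i in seq_len(n)) {
    x <- train_corpus$calls[[i]]
    calls[[i]] <- if (use_reverb[i]) {
      apply_reverb(x, irs[[pick_ir[i]]])
    } else {
      calibrate_level(add_noise_at_snr(x, pick_noise[i],
                                       rng_seed = derive_seed(seed, 500 + i)))
    }
  }
  degraded <- structure(list(calls = calls, labels = train_corpus$labels,
                             class_specs = train_corpus$class_specs,
                             rng_seed = train_corpus$rng_seed),
                        class = "call_corpus")
  dg <- corpus_cochleagrams(degraded, config$grid, config$frontend)
  if (config$keep_clean_in_training)
    list(cochleagrams = c(clean$cochleagrams, dg$cochleagrams),
         labels = c(clean$labels, dg$labels))
  else dg
}

#' Run the training-by-mechanism-by-condition experiment matrix
#'
#' The package's end-to-end study: generates a labeled synthetic corpus,
#' splits it into disjoint training and test halves, trains
#' `instantiations` non-overlapping one-vs-rest models per call type for
#' every requested training condition and matching mode, evaluates every
#' model on every test condition (clean, each SNR, each T30), applies the
#' requested top-down kappa policies, and tabulates AUC and d-prime per
#' (training condition, mechanism, test condition, call type,
#' instantiation), together with the d-prime benefit over the clean-trained
#' core model.  Everything is derived deterministically from `config$seed`.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage timings.
#' @return An object of class `mif_experiment`: list with
#'   * `results` -- the tidy results table described above;
#'   * `kappa_table` -- per condition, the MI-optimal threshold ratio and
#'     the median cochleagram mu/sigma of the tuning stimuli;
#'   * `kappa_map` -- the fitted mu/sigma-to-kappa map (when a proxy
#'     mechanism ran, else `NULL`);
#'   * `ensembles` -- the fitted `mif_ensemble`s, keyed by
#'     `<train_condition>/<mode>/<call_type>`;
#'   * `config`.
#' @export
run_experiment_matrix <- function(config = experiment_config(),
                                  verbose = FALSE) {
  assert_that(inherits(config, "experiment_config"),
              "config must be an experiment_config")
  seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  tick <- function(label) {
    say("[%6.1f s] %s", as.numeric(difftime(Sys.time(), t0, units = "secs")),
        label)
  }

  corpus <- make_corpus(config$classes, config$n_per_class,
                        rng_seed = derive_seed(seed, 1),
                        sample_rate = config$sample_rate)
  sp <- split_corpus(corpus, config$train_frac,
                     rng_seed = derive_seed(seed, 2))
  conds <- condition_table(config)
  irs <- list()
  for (i in seq_len(nrow(conds))) {
    if (conds$test_type[i] == "reverb")
      irs[[conds$condition[i]]] <- synth_impulse_response(
        conds$t30_ms[i], sample_rate = config$sample_rate,
        rng_seed = derive_seed(seed, 10 + i))
  }
  tick("corpus generated")

  # test cochleagrams per condition
  test_sets <- list()
  for (i in seq_len(nrow(conds))) {
    cond <- conds[i, ]
    degraded <- degrade_for_condition(sp$test, cond, irs,
                                      derive_seed(seed, 100 + i))
    test_sets[[cond$condition]] <- corpus_cochleagrams(degraded, config$grid,
                                                       config$frontend)
  }
  tick("test cochleagrams computed")

  # kappa tuning stimuli: a balanced subset of the training calls, degraded
  # per condition (tuning never touches the test set)
  need_kappa <- any(vapply(config$mechanisms, mechanism_policy,
                           character(1)) != "off")
  tune_sets <- list()
  if (need_kappa) {
    set.seed(derive_seed(seed, 3))
    idx <- unlist(lapply(unique(sp$train$labels), function(cl) {
      ii <- which(sp$train$labels == cl)
      sort(sample(ii, min(config$n_tune_per_class, length(ii))))
    }))
    tune_corpus <- structure(list(calls = sp$train$calls[idx],
                                  labels = sp$train$labels[idx],
                                  class_specs = sp$train$class_specs,
                                  rng_seed = sp$train$rng_seed),
                             class = "call_corpus")
    for (i in seq_len(nrow(conds))) {
      cond <- conds[i, ]
      degraded <- degrade_for_condition(tune_corpus, cond, irs,
                                        derive_seed(seed, 200 + i))
      tune_sets[[cond$condition]] <- corpus_cochleagrams(degraded,
                                                         config$grid,
                                                         config$frontend)
    }
    tick("kappa tuning cochleagrams computed")
  }

  # fit ensembles per (train_condition, mode, call type)
  class_names <- vapply(config$classes, function(s) s$name, character(1))
  modes_needed <- unique(vapply(config$mechanisms, mechanism_mode,
                                character(1)))
  ensembles <- list()
  for (tc in config$train_conditions) {
    train_set <- build_training_set(sp$train, tc, config, irs,
                                    derive_seed(seed, 4))
    for (mode in modes_needed) {
      for (ci in seq_along(class_names)) {
        ct <- class_names[ci]
        key <- paste(tc, mode, ct, sep = "/")
        tcorp <- training_corpus(train_set$cochleagrams, train_set$labels,
                                 ct, condition = tc)
        ensembles[[key]] <- mif_train_ensemble(
          tcorp, k = config$instantiations,
          n_candidates = config$n_candidates, mode = mode,
          size_bounds = config$size_bounds, max_set = config$max_set,
          rng_seed = derive_seed(seed, 1000 + 37 * ci))
        tick(sprintf("trained %s", key))
      }
    }
  }

  # oracle kappa per (train_condition, mode, condition); proxy map from the
  # per-condition (median mu/sigma, optimal kappa) pairs
  kappa_oracle <- list()
  kappa_rows <- list()
  kappa_map <- NULL
  if (need_kappa) {
    for (tc in config$train_conditions) {
      for (mode in modes_needed) {
        mods <- setNames(lapply(class_names, function(ct)
          ensembles[[paste(tc, mode, ct, sep = "/")]]), class_names)
        for (i in seq_len(nrow(conds))) {
          cond <- conds[i, ]
          ts <- tune_sets[[cond$condition]]
          tab <- vm_table(mods, ts$cochleagrams, mode)
          opt <- optimal_threshold_ratio(tab, ts$labels, config$kappa_grid)
          kappa_oracle[[paste(tc, mode, cond$condition, sep = "/")]] <- opt$kappa
          proxy_med <- stats::median(vapply(ts$cochleagrams, function(cc)
            estimate_snr_proxy(cc)$ratio, numeric(1)))
          kappa_rows[[length(kappa_rows) + 1L]] <- cbind(
            data.frame(train_condition = tc, mode = mode), cond,
            data.frame(kappa_opt = opt$kappa, mi_bits = opt$mi_bits,
                       proxy_median = proxy_med))
        }
      }
    }
    ktab <- do.call(rbind, kappa_rows)
    first <- ktab[ktab$train_condition == config$train_conditions[1] &
                    ktab$mode == mechanism_mode(config$mechanisms[
                      vapply(config$mechanisms, mechanism_policy,
                             character(1)) != "off"][1]), ]
    kappa_map <- fit_kappa_map(first$proxy_median, first$kappa_opt,
                               range(config$kappa_grid))
    tick("kappa tuned")
  }

  # evaluate: one vm_table per (train_condition, mode, condition), shared
  # by every kappa policy
  rows <- list()
  for (tc in config$train_conditions) {
    for (mode in modes_needed) {
      mods <- setNames(lapply(class_names, function(ct)
        ensembles[[paste(tc, mode, ct, sep = "/")]]), class_names)
      for (i in seq_len(nrow(conds))) {
        cond <- conds[i, ]
        ts <- test_sets[[cond$condition]]
        tab <- vm_table(mods, ts$cochleagrams, mode)
        for (mech in config$mechanisms) {
          if (mechanism_mode(mech) != mode) next
          policy <- mechanism_policy(mech)
          kappa <- switch(
            policy,
            off = 1,
            oracle = kappa_oracle[[paste(tc, mode, cond$condition, sep = "/")]],
            proxy = predict(kappa_map, lapply(ts$cochleagrams,
                                              estimate_snr_proxy)))
          sc <- table_scores(tab, kappa)
          for (g in sc$by_model) {
            within <- ts$labels == g$call_type
            auc <- auc_from_scores(g$scores[within], g$scores[!within])
            rows[[length(rows) + 1L]] <- cbind(
              data.frame(train_condition = tc, mechanism = mech), cond,
              data.frame(call_type = g$call_type,
                         instantiation = g$instantiation, auc = auc,
                         dprime = dprime_from_auc(
                           auc, n_pairs = sum(within) * sum(!within))))
          }
        }
      }
      tick(sprintf("evaluated %s/%s", tc, mode))
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  # benefit relative to the clean-trained core model, matched on test
  # condition, call type and instantiation
  base <- results[results$train_condition == "clean" &
                    results$mechanism == "core", ]
  if (nrow(base) > 0) {
    key <- function(d) paste(d$condition, d$call_type, d$instantiation)
    results$benefit <- results$dprime - base$dprime[match(key(results),
                                                          key(base))]
  } else {
    results$benefit <- NA_real_
  }

  structure(list(results = results,
                 kappa_table = if (length(kappa_rows))
                   do.call(rbind, kappa_rows) else NULL,
                 kappa_map = kappa_map, ensembles = ensembles,
                 config = config),
            class = "mif_experiment")
}

#' @export
print.mif_experiment <- function(x, ...) {
  cat(sprintf("<mif_experiment> %d result rows (%s x %s mechanisms x %d conditions x %d call types x %d instantiations)\n",
              nrow(x$results),
              paste(x$config$train_conditions, collapse = "/"),
              paste(x$config$mechanisms, collapse = "/"),
              length(unique(x$results$condition)),
              length(unique(x$results$call_type)),
              x$config$instantiations))
  agg <- stats::aggregate(dprime ~ mechanism + condition, x$results, mean)
  cat("\nMean d-prime by mechanism and condition:\n")
  print(utils::head(agg[order(agg$condition, agg$mechanism), ], 40),
        row.names = FALSE, digits = 3)
  invisible(x)
}
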