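#' Assemble a training corpus of cochleagrams
#'
#' One-vs-rest training data for a single call type: the within-class
#' cochleagrams versus all other (outside-class) cochleagrams, all sharing
#' one CF grid.
#'
#' @param cochleagrams list of [compute_cochleagram()] cochleagrams.
#' @param labels character vector of call-type labels, one per cochleagram.
#' @param call_type the within-class label.
#' @param condition tag for the training condition (`"clean"`, `"noise"`,
#'   `"reverb"`, `"mixed"`).
#' @return An object of class `training_corpus` with `within`, `outside`,
#'   `call_type`, `condition`.
#' @export
training_corpus <- function(cochleagrams, labels, call_type,
                            condition = "clean") {
  assert_that(length(cochleagrams) == length(labels),
              "labels must match cochleagrams")
  assert_that(call_type %in% labels, "call_type absent from labels")
  assert_that(!all(labels == call_type), "no outside-class cochleagrams")
  structure(list(within = cochleagrams[labels == call_type],
                 outside = cochleagrams[labels != call_type],
                 call_type = call_type, condition = condition),
            class = "training_corpus")
}

#' Sample candidate feature detectors
#'
#' Cuts `n` rectangular patches from the within-class cochleagrams, each
#' with uniformly drawn onset time, duration, bandwidth and channel
#' position within the size bounds (clipped to what the source cochleagram
#' can provide).  Constant (zero-variance) patches carry no feature and are
#' re-drawn.  Fully reproducible from the seed.
#'
#' @param corpus a [training_corpus()].
#' @param n number of candidates.
#' @param size_bounds list with `duration_ms` and `bandwidth_oct` ranges;
#'   the defaults (50-300 ms, 0.5-3 octaves) bracket the scales at which
#'   informative vocalization features live.
#' @param rng_seed integer seed.
#' @return An object of class `candidate_pool`: list with `candidates`
#'   (list of untrained [feature_detector()]) and `rng_seed`.
#' @export
sample_candidates <- function(corpus, n,
                              size_bounds = list(duration_ms = c(50, 300),
                                                 bandwidth_oct = c(0.5, 3)),
                              rng_seed = 1L) {
  assert_that(n > 0, "n must be positive")
  assert_that(inherits(corpus, "training_corpus"), "corpus must be a training_corpus")
  src_list <- corpus$within
  fr <- src_list[[1]]$frame_rate
  step <- src_list[[1]]$grid$step_octaves
  set.seed(as.integer(rng_seed))
  candidates <- vector("list", n)
  k <- 0L; tries <- 0L; max_tries <- 100L * n
  dur_b <- size_bounds$duration_ms
  bw_b <- size_bounds$bandwidth_oct
  while (k < n && tries < max_tries) {
    tries <- tries + 1L
    src_i <- sample.int(length(src_list), 1)
    src <- src_list[[src_i]]
    nt <- nrow(src$values); nc <- ncol(src$values)
    dur_hi <- min(dur_b[2], nt / fr * 1000)
    if (dur_hi < dur_b[1] - 1e-9) next        # source too short for the bounds
    dur_ms <- stats::runif(1, dur_b[1], dur_hi)
    T <- max(2L, min(nt, as.integer(round(dur_ms / 1000 * fr))))
    span_oct <- (nc - 1) * step
    bw_hi <- min(bw_b[2], span_oct)
    if (bw_hi < bw_b[1] - 1e-9) next
    bw_oct <- stats::runif(1, bw_b[1], bw_hi)
    C <- max(2L, min(nc, as.integer(round(bw_oct / step)) + 1L))
    t0 <- sample.int(nt - T + 1L, 1)
    c0 <- sample.int(nc - C + 1L, 1)
    patch <- src$values[t0:(t0 + T - 1L), c0:(c0 + C - 1L), drop = FALSE]
    if (pop_sd(patch) <= 0) next              # silent patch, re-draw
    k <- k + 1L
    fd <- feature_detector(patch, c(c0, c0 + C - 1L), frame_rate = fr,
                           id = sprintf("cand%05d", k))
    attr(fd, "source_index") <- src_i
    attr(fd, "onset_frame") <- t0
    candidates[[k]] <- fd
  }
  if (k < n)
    stop("could not sample ", n, " candidates within the size bounds", call. = FALSE)
  structure(list(candidates = candidates, rng_seed = rng_seed),
            class = "candidate_pool")
}

# MI (bits) of the 2x2 detection-by-class table, vectorized over thresholds
mi_from_counts <- function(hits, nw, fas, no) {
  n <- nw + no
  p <- cbind(hits, nw - hits, fas, no - fas) / n
  pw <- nw / n
  pdet <- (hits + fas) / n
  pe <- cbind(pw * pdet, pw * (1 - pdet), (1 - pw) * pdet, (1 - pw) * (1 - pdet))
  term <- p * log2(p / pe)
  term[p == 0] <- 0
  rowSums(term)
}

#' Learn a detection threshold by mutual-information maximization
#'
#' Scans candidate thresholds over the sorted union of the observed
#' response maxima; at each threshold the binary detection output
#' (`max Vm >= threshold`) forms a 2x2 contingency with the stimulus class,
#' whose empirical mutual information (in bits) is computed.  Returns the
#' MI-maximizing threshold, taking the largest such threshold on ties.
#'
#' @param vm_max_within,vm_max_outside response maxima for within- and
#'   outside-class stimuli.
#' @return List with `threshold` and `mi_bits`.
#' @examples
#' learn_threshold(rep(5, 10), rep(1, 10))  # theta = 5, MI = 1 bit
#' @export
learn_threshold <- function(vm_max_within, vm_max_outside) {
  w <- as.numeric(vm_max_within); o <- as.numeric(vm_max_outside)
  assert_that(length(w) > 0 && length(o) > 0, "both classes must be non-empty")
  thr <- sort(unique(c(w, o)))
  ws <- sort(w); os <- sort(o)
  hits <- length(w) - findInterval(thr, ws, left.open = TRUE)
  fas <- length(o) - findInterval(thr, os, left.open = TRUE)
  mi <- mi_from_counts(hits, length(w), fas, length(o))
  # largest maximizing threshold; ties judged to 1e-12 bits, since distinct
  # contingency tables can reach the same MI by different arithmetic
  best <- max(which(mi >= max(mi) - 1e-12))
  list(threshold = thr[best], mi_bits = mi[best])
}

#' Learn a log-likelihood voting weight
#'
#' The weight is the smoothed base-2 log-likelihood ratio of detection
#' given class membership:
#' `log2((hits + 1)/(n_within + 2)) - log2((fas + 1)/(n_outside + 2))`
#' (add-one smoothing keeps the weight finite at 0% or 100% detection
#' rates).
#'
#' @param detections_within,detections_outside binary (0/1) detection
#'   vectors for within- and outside-class stimuli.
#' @return The weight (scalar, bits).
#' @export
learn_weight <- function(detections_within, detections_outside) {
  dw <- as.numeric(detections_within); do_ <- as.numeric(detections_outside)
  assert_that(length(dw) > 0 && length(do_) > 0, "both classes must be non-empty")
  log2((sum(dw) + 1) / (length(dw) + 2)) - log2((sum(do_) + 1) / (length(do_) + 2))
}

# Response maxima, thresholds, weights, MI and detection patterns for every
# candidate in a pool; the expensive part of training, computed once and
# shared by all instantiations.
candidate_stats <- function(candidates, corpus, mode = "core") {
  cochs <- c(corpus$within, corpus$outside)
  nw <- length(corpus$within); ns <- length(cochs)
  ncand <- length(candidates)
  gs <- lapply(candidates, function(fd) normalize_strf(fd$strf))
  lo <- vapply(candidates, function(fd) fd$channel_span[1], integer(1))
  vmmax <- matrix(NA_real_, ncand, ns)
  for (s in seq_len(ns))
    vmmax[, s] <- cpp_vm_max_batch(prep_coch_matrix(cochs[[s]], mode), gs, lo,
                                   if (mode == "cgc_local") 1L else 0L)
  threshold <- numeric(ncand); mi <- numeric(ncand); weight <- numeric(ncand)
  det <- matrix(FALSE, ncand, ns)
  for (i in seq_len(ncand)) {
    fit <- learn_threshold(vmmax[i, seq_len(nw)], vmmax[i, -seq_len(nw)])
    threshold[i] <- fit$threshold; mi[i] <- fit$mi_bits
    det[i, ] <- vmmax[i, ] >= fit$threshold
    weight[i] <- learn_weight(det[i, seq_len(nw)], det[i, -seq_len(nw)])
  }
  list(vmmax = vmmax, threshold = threshold, mi = mi, weight = weight,
       det = det, n_within = nw, n_outside = ns - nw)
}

#' Greedy most-informative-feature search
#'
#' Ranks candidates by their individual mutual information with the
#' stimulus class, then repeatedly adds the best-ranked unused candidate
#' whose admission (i) is not redundant with the current set -- the MI
#' between its detection pattern and any member's pattern must stay below
#' `redundancy_frac` of its own class MI -- and (ii) strictly increases the
#' voting-stage hit rate without increasing the false-alarm rate, under the
#' decision rule "within-class iff the weighted vote sum is positive".
#' Stops when no candidate qualifies or the set reaches `max_set` (20, the
#' cap on an MIF set).  Only candidates with positive MI and positive
#' weight are eligible.
#'
#' @param pool a [sample_candidates()] pool.
#' @param corpus the [training_corpus()] the pool was cut from.
#' @param mode normalization mode used for training responses (see
#'   [vm_response()]).
#' @param max_set maximum MIF-set size.
#' @param redundancy_frac redundancy threshold as a fraction of a
#'   candidate's class MI.
#' @param stats precomputed [candidate_stats] (internal reuse); computed
#'   when `NULL`.
#' @param exclude_ids candidate ids barred from selection (used to train
#'   non-overlapping instantiations).
#' @param instantiation instantiation index recorded on the model.
#' @return An object of class `mif_model`; see [mif_train()].
#' @export
greedy_mif_search <- function(pool, corpus, mode = "core", max_set = 20,
                              redundancy_frac = 0.5, stats = NULL,
                              exclude_ids = NULL, instantiation = 1L) {
  assert_that(inherits(pool, "candidate_pool"), "pool must be a candidate_pool")
  if (is.null(stats)) stats <- candidate_stats(pool$candidates, corpus, mode)
  ids <- vapply(pool$candidates, function(f) f$id, character(1))
  nw <- stats$n_within; no <- stats$n_outside
  eligible <- stats$mi > 0 & stats$weight > 0 & !(ids %in% exclude_ids)
  ranked <- order(-stats$mi, seq_along(ids))
  ranked <- ranked[eligible[ranked]]

  selected <- integer(0)
  vw <- numeric(nw); vo <- numeric(no)
  hit <- 0; fa <- 0
  traj <- list()
  repeat {
    if (length(selected) >= max_set) break
    added <- FALSE
    for (i in ranked) {
      if (i %in% selected) next
      redundant <- any(vapply(selected, function(s2)
        mi_binary(stats$det[i, ], stats$det[s2, ]) >
          redundancy_frac * stats$mi[i], logical(1)))
      if (redundant) next
      new_vw <- vw + stats$weight[i] * stats$det[i, seq_len(nw)]
      new_vo <- vo + stats$weight[i] * stats$det[i, -seq_len(nw)]
      new_hit <- mean(new_vw > 0); new_fa <- mean(new_vo > 0)
      if (new_hit > hit && new_fa <= fa) {
        selected <- c(selected, i)
        vw <- new_vw; vo <- new_vo; hit <- new_hit; fa <- new_fa
        traj[[length(traj) + 1L]] <- data.frame(
          iteration = length(selected), candidate = ids[i],
          mi_bits = stats$mi[i], hit = hit, fa = fa)
        added <- TRUE
        break
      }
    }
    if (!added) break
  }
  if (length(selected) == 0)
    warning("no candidate improved the voting decision; returning an empty model")
  fds <- lapply(selected, function(i) {
    fd <- pool$candidates[[i]]
    fd$threshold <- stats$threshold[i]
    fd$weight <- stats$weight[i]
    fd
  })
  grid <- if (length(corpus$within)) corpus$within[[1]]$grid else NULL
  structure(list(fds = fds, call_type = corpus$call_type, mode = mode,
                 condition = corpus$condition,
                 instantiation = as.integer(instantiation),
                 max_set = max_set,
                 trajectory = if (length(traj)) do.call(rbind, traj) else
                   data.frame(iteration = integer(0), candidate = character(0),
                              mi_bits = numeric(0), hit = numeric(0),
                              fa = numeric(0)),
                 grid = grid,
                 n_within = nw, n_outside = no,
                 rng_seed = pool$rng_seed),
            class = "mif_model")
}

#' Fit a most-informative-feature categorization model
#'
#' The top-level fitting function for one call type: samples candidate
#' spectrotemporal patches from the within-class cochleagrams, learns each
#' candidate's MI-optimal detection threshold and log-likelihood weight,
#' and greedily assembles the most informative, least redundant feature
#' set ([greedy_mif_search()]).
#'
#' @param corpus a [training_corpus()].
#' @param n_candidates size of the initial candidate pool.
#' @param mode normalization mode used both in training and (by default)
#'   at prediction time: `"core"`, `"cgc_local"`, `"cgc_global"`.
#' @param size_bounds candidate size bounds (see [sample_candidates()]).
#' @param max_set maximum MIF-set size (default 20).
#' @param redundancy_frac redundancy threshold fraction.
#' @param rng_seed integer seed for candidate sampling.
#' @return An object of class `mif_model` with components `fds` (ordered
#'   feature detectors with thresholds and weights), `call_type`, `mode`,
#'   `condition`, `trajectory` (per-iteration candidate id, MI, hit and
#'   false-alarm rates), and bookkeeping fields.  Methods: `print`,
#'   `summary`, `coef`, `predict`, `plot`.
#' @seealso [mif_train_ensemble()] for non-overlapping instantiations,
#'   [predict.mif_model()], [voting_score()]
#' @export
mif_train <- function(corpus, n_candidates = 1000, mode = "core",
                      size_bounds = list(duration_ms = c(50, 300),
                                         bandwidth_oct = c(0.5, 3)),
                      max_set = 20, redundancy_frac = 0.5, rng_seed = 1L) {
  pool <- sample_candidates(corpus, n_candidates, size_bounds, rng_seed)
  greedy_mif_search(pool, corpus, mode = mode, max_set = max_set,
                    redundancy_frac = redundancy_frac)
}

#' Fit non-overlapping model instantiations
#'
#' Trains `k` models for the same call type from one shared candidate pool,
#' excluding from each instantiation every feature already selected by the
#' previous ones, so the MIF sets are pairwise disjoint.  The expensive
#' candidate responses are computed once and shared.
#'
#' @inheritParams mif_train
#' @param k number of instantiations (default 5).
#' @return An object of class `mif_ensemble`: a list of `mif_model`s (in
#'   instantiation order) with shared metadata.  If the pool is exhausted
#'   before `k` sets are found, fewer models are returned with a warning.
#' @export
mif_train_ensemble <- function(corpus, k = 5, n_candidates = 1000,
                               mode = "core",
                               size_bounds = list(duration_ms = c(50, 300),
                                                  bandwidth_oct = c(0.5, 3)),
                               max_set = 20, redundancy_frac = 0.5,
                               rng_seed = 1L) {
  pool <- sample_candidates(corpus, n_candidates, size_bounds, rng_seed)
  stats <- candidate_stats(pool$candidates, corpus, mode)
  models <- list()
  used <- character(0)
  for (i in seq_len(k)) {
    m <- withCallingHandlers(
      greedy_mif_search(pool, corpus, mode = mode, max_set = max_set,
                        redundancy_frac = redundancy_frac, stats = stats,
                        exclude_ids = used, instantiation = i),
      warning = function(w) invokeRestart("muffleWarning"))
    if (length(m$fds) == 0) {
      warning("candidate pool exhausted after ", length(models),
              " instantiation(s)")
      break
    }
    used <- c(used, vapply(m$fds, function(f) f$id, character(1)))
    models[[length(models) + 1L]] <- m
  }
  structure(list(models = models, call_type = corpus$call_type, mode = mode,
                 condition = corpus$condition, rng_seed = rng_seed),
            class = "mif_ensemble")
}
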