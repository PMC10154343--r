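# Shared fixtures, all generated in code.  Expensive objects are memoized
# so several test files can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a small random cochleagram on a default-spaced grid
rand_coch <- function(n_t = 60, n_ch = 12, seed = 1, offset = 0) {
  set.seed(seed)
  as_cochleagram(matrix(runif(n_t * n_ch), n_t, n_ch) + offset)
}

# a two-class labeled cochleagram set (chut-like sweep vs wheek-like tone),
# enough to train small models quickly
tiny_labeled_cochs <- function() {
  memoize("tiny_cochs", {
    classes <- default_call_classes()[c("chut", "wheek")]
    corp <- make_corpus(classes, n_per_class = 6, rng_seed = 42)
    corpus_cochleagrams(corp, make_cf_grid(200, 6400, 0.1))
  })
}

# the reference end-to-end study used by the acceptance tests (criteria on
# the synthetic corpus: 4 classes, 100 calls/class, 5 instantiations)
acceptance_study <- function() {
  memoize("acceptance_study", {
    cfg <- experiment_config(n_per_class = 100, instantiations = 5,
                             n_candidates = 200,
                             t30_grid_ms = c(7, 128, 644), seed = 101)
    suppressWarnings(run_experiment_matrix(cfg))
  })
}

# a hand-built model whose detections we control exactly: each detector is
# a patch of the target cochleagram (fires at a tiny threshold) or carries
# an unreachably high threshold (never fires)
build_toy_model <- function(coch, weights, fire) {
  fds <- lapply(seq_along(weights), function(j) {
    patch <- coch$values[(5 * j):(5 * j + 7), 2:5]
    feature_detector(patch, c(2, 5),
                     threshold = if (fire[j]) 1e-6 else 1e6,
                     weight = weights[j], id = paste0("toy", j))
  })
  structure(list(fds = fds, call_type = "toy", mode = "cgc_local",
                 condition = "clean", instantiation = 1L, max_set = 20,
                 trajectory = data.frame(), grid = coch$grid,
                 n_within = 1, n_outside = 1, rng_seed = 1L),
            class = "mif_model")
}

# a hand-constructed response table with two one-detector models whose
# MI-optimal threshold scale is exactly 1 (a plateau with nearest-1
# tie-break); scaling all maxima rescales the optimum exactly
toy_vm_table <- function(scale = 1) {
  vmmax <- rbind(a = c(1.0, 1.0, 1.0, 1.0, 0.4, 0.4, 0.4, 0.4),
                 b = c(0.4, 0.4, 0.4, 0.4, 1.0, 1.0, 1.0, 1.0)) * scale
  structure(list(vmmax = vmmax, threshold = c(1, 1), weight = c(1, 1),
                 call_type = c("a", "b"), instantiation = c(1L, 1L),
                 fd_id = c("fa", "fb"), mode = "core", n_stimuli = 8L),
            class = "vm_table")
}

# independent brute-force oracles -----------------------------------------

# exhaustive cut-point scan for the MI-optimal threshold, written against
# the entropy identity MI = H(class) + H(det) - H(class, det)
oracle_threshold <- function(w, o) {
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  cls <- c(rep(1, length(w)), rep(0, length(o)))
  v <- c(w, o)
  thr_all <- sort(unique(v))
  mi_all <- vapply(thr_all, function(thr) {
    det <- as.integer(v >= thr)
    n <- length(v)
    joint <- c(sum(cls & det), sum(cls & !det), sum(!cls & det),
               sum(!cls & !det)) / n
    ent(c(mean(cls), 1 - mean(cls))) + ent(c(mean(det), 1 - mean(det))) -
      ent(joint)
  }, numeric(1))
  # same largest-maximizer convention (ties to 1e-12 bits) as the package
  best <- max(which(mi_all >= max(mi_all) - 1e-12))
  list(threshold = thr_all[best], mi_bits = mi_all[best])
}

# pairwise-count AUC
oracle_auc <- function(w, o) {
  cmp <- outer(w, o, ">") + 0.5 * outer(w, o, "==")
  mean(cmp)
}

# naive sliding-window demeaned-template match (core mode)
oracle_vm_core <- function(strf, block) {
  g <- (strf - mean(strf)) / sqrt(mean((strf - mean(strf))^2))
  TT <- nrow(strf)
  vapply(seq_len(nrow(block) - TT + 1), function(s)
    mean(block[s:(s + TT - 1), , drop = FALSE] * g), numeric(1))
}

# multi-class confusion MI via the entropy identity
oracle_mi_confusion <- function(true, pred) {
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  lev <- union(unique(true), unique(pred))
  joint <- table(factor(true, lev), factor(pred, lev)) / length(true)
  ent(rowSums(joint)) + ent(colSums(joint)) - ent(as.numeric(joint))
}
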