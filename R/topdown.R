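#' Cochleagram statistics as an SNR proxy
#'
#' The mean and standard deviation over all time-frequency bins of a
#' cochleagram, and their ratio.  Additive noise raises the activation
#' floor everywhere (mean up) while flattening the pattern (SD down), so
#' mu/sigma grows as the acoustic SNR falls -- a biologically computable
#' stand-in for the SNR that can drive top-down threshold modulation.
#'
#' @param coch a cochleagram.
#' @return An object of class `snr_proxy`: list with `mu`, `sigma`,
#'   `ratio`.
#' @export
estimate_snr_proxy <- function(coch) {
  assert_that(inherits(coch, "cochleagram"), "coch must be a cochleagram")
  mu <- mean(coch$values)
  sigma <- pop_sd(coch$values)
  if (sigma <= 0) stop("degenerate input: zero-variance cochleagram", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, ratio = mu / sigma),
            class = "snr_proxy")
}

#' Precompute detector response maxima for a stimulus set
#'
#' Tabulates, for every feature detector of every model, the maximum
#' membrane-potential response on every stimulus.  The table is the basis
#' of all voting-stage evaluation: detections at any threshold scale
#' `kappa` follow from it without re-running the cross-correlations
#' (`detected iff vmmax >= kappa * threshold`).
#'
#' @param models a named list of `mif_ensemble`s (or `mif_model`s), one
#'   entry per call type.
#' @param cochleagrams list of cochleagrams.
#' @param mode normalization mode used for the responses.
#' @return An object of class `vm_table`: list with `vmmax` (detectors x
#'   stimuli matrix), `threshold`, `weight`, `call_type`, `instantiation`,
#'   `fd_id` (per-detector metadata), `mode`, `n_stimuli`.
#' @export
vm_table <- function(models, cochleagrams, mode = NULL) {
  flat <- list(); meta_ct <- character(0); meta_in <- integer(0)
  for (ct in names(models)) {
    m <- models[[ct]]
    mods <- if (inherits(m, "mif_ensemble")) m$models else list(m)
    for (mm in mods) {
      for (fd in mm$fds) {
        flat[[length(flat) + 1L]] <- fd
        meta_ct <- c(meta_ct, ct)
        meta_in <- c(meta_in, mm$instantiation)
      }
      if (is.null(mode)) mode <- mm$mode
    }
  }
  assert_that(length(flat) > 0, "no feature detectors in the supplied models")
  gs <- lapply(flat, function(fd) normalize_strf(fd$strf))
  lo <- vapply(flat, function(fd) fd$channel_span[1], integer(1))
  vmmax <- matrix(NA_real_, length(flat), length(cochleagrams))
  for (s in seq_along(cochleagrams))
    vmmax[, s] <- cpp_vm_max_batch(prep_coch_matrix(cochleagrams[[s]], mode),
                                   gs, lo,
                                   if (mode == "cgc_local") 1L else 0L)
  structure(list(vmmax = vmmax,
                 threshold = vapply(flat, function(f) f$threshold, numeric(1)),
                 weight = vapply(flat, function(f) f$weight, numeric(1)),
                 call_type = meta_ct, instantiation = meta_in,
                 fd_id = vapply(flat, function(f) f$id, character(1)),
                 mode = mode, n_stimuli = length(cochleagrams)),
            class = "vm_table")
}

# normalized voting scores from a vm_table
# kappa: scalar or one value per stimulus
# returns list(by_model = list of (call_type, instantiation, scores),
#              by_class = stimuli x classes matrix of instantiation means)
table_scores <- function(tab, kappa = 1) {
  kappa <- rep_len(kappa, tab$n_stimuli)
  det <- tab$vmmax >= tcrossprod(tab$threshold, kappa)
  groups <- split(seq_along(tab$threshold),
                  paste(tab$call_type, tab$instantiation, sep = "\r"))
  by_model <- lapply(groups, function(idx) {
    w <- tab$weight[idx]
    list(call_type = tab$call_type[idx[1]],
         instantiation = tab$instantiation[idx[1]],
         scores = as.numeric(crossprod(det[idx, , drop = FALSE], w)) / sum(w))
  })
  classes <- unique(tab$call_type)
  by_class <- sapply(classes, function(ct) {
    sc <- lapply(by_model[vapply(by_model, function(g) g$call_type == ct,
                                 logical(1))], `[[`, "scores")
    Reduce(`+`, sc) / length(sc)
  })
  if (is.null(dim(by_class))) by_class <- matrix(by_class, nrow = tab$n_stimuli)
  colnames(by_class) <- classes
  list(by_model = by_model, by_class = by_class)
}

# multi-class mutual information (bits) between two label vectors
mi_confusion <- function(true, pred) {
  lev <- union(unique(true), unique(pred))
  tab <- table(factor(true, lev), factor(pred, lev))
  p <- tab / sum(tab)
  pr <- rowSums(p); pc <- colSums(p)
  pe <- outer(pr, pc)
  keep <- p > 0
  sum(p[keep] * log2(p[keep] / pe[keep]))
}

#' Optimal top-down threshold ratio for a condition
#'
#' Scans a grid of global threshold scales `kappa`.  At each `kappa`, every
#' stimulus is assigned the call type whose one-vs-rest normalized voting
#' response (averaged over instantiations) is largest, and the mutual
#' information between true and predicted call types is computed from the
#' confusion matrix.  Returns the MI-maximizing `kappa`, preferring the
#' value nearest 1 on ties.
#'
#' @param tab a [vm_table()] for the condition's labeled stimuli, covering
#'   at least two call types.
#' @param labels true call-type labels, one per stimulus.
#' @param kappa_grid grid of candidate scales (default 0.25 to 1.20 in
#'   steps of 0.01).
#' @return List of class `threshold_ratio`: `kappa`, `mi_bits`,
#'   `mi_by_kappa` (the full scan).
#' @export
optimal_threshold_ratio <- function(tab, labels,
                                    kappa_grid = seq(0.25, 1.2, by = 0.01)) {
  assert_that(inherits(tab, "vm_table"), "tab must be a vm_table")
  assert_that(length(labels) == tab$n_stimuli, "labels must match stimuli")
  assert_that(length(unique(tab$call_type)) >= 2,
              "need models for at least two call types")
  assert_that(length(kappa_grid) > 0 && all(kappa_grid > 0),
              "kappa_grid must be positive")
  mi <- vapply(kappa_grid, function(k) {
    sc <- table_scores(tab, k)$by_class
    pred <- colnames(sc)[max.col(sc, ties.method = "first")]
    mi_confusion(labels, pred)
  }, numeric(1))
  if (max(mi) <= 0) {
    warning("predictions carry no class information at any kappa; returning kappa = 1")
    return(structure(list(kappa = 1, mi_bits = 0, mi_by_kappa = mi),
                     class = "threshold_ratio"))
  }
  best <- which(mi == max(mi))
  kappa <- kappa_grid[best[which.min(abs(kappa_grid[best] - 1))]]
  structure(list(kappa = kappa, mi_bits = max(mi), mi_by_kappa = mi),
            class = "threshold_ratio")
}

#' @export
print.threshold_ratio <- function(x, ...) {
  cat(sprintf("<threshold_ratio> kappa = %.3g (MI = %.3f bits)\n",
              x$kappa, x$mi_bits))
  invisible(x)
}

#' Fit the mu/sigma-to-kappa map
#'
#' Linear map `kappa = a + b * (mu/sigma)` fitted by least squares to
#' (proxy, optimal kappa) training pairs, with predictions clipped to the
#' kappa-grid range.  Degenerate inputs (fewer than two distinct proxy
#' values) fall back to the median kappa with a warning.
#'
#' @param proxies numeric mu/sigma values (or a list of [estimate_snr_proxy()]
#'   objects).
#' @param kappas optimal kappa for each proxy.
#' @param kappa_range clip range for predictions.
#' @return An object of class `kappa_map`; `predict(map, proxy)` returns
#'   per-stimulus kappa values.
#' @export
fit_kappa_map <- function(proxies, kappas, kappa_range = c(0.25, 1.2)) {
  if (is.list(proxies))
    proxies <- vapply(proxies, function(p) p$ratio, numeric(1))
  assert_that(length(proxies) == length(kappas) && length(proxies) >= 1,
              "proxies and kappas must be matched and non-empty")
  if (length(unique(proxies)) < 2) {
    warning("degenerate proxy values; falling back to the median kappa")
    return(structure(list(intercept = stats::median(kappas), slope = 0,
                          kappa_range = kappa_range, fallback = TRUE),
                     class = "kappa_map"))
  }
  fit <- stats::lm.fit(cbind(1, proxies), kappas)
  structure(list(intercept = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2]),
                 kappa_range = kappa_range, fallback = FALSE),
            class = "kappa_map")
}

#' @export
print.kappa_map <- function(x, ...) {
  cat(sprintf("<kappa_map> kappa = %.4g %+.4g * (mu/sigma), clipped to [%g, %g]%s\n",
              x$intercept, x$slope, x$kappa_range[1], x$kappa_range[2],
              if (x$fallback) " (median fallback)" else ""))
  invisible(x)
}

#' @export
predict.kappa_map <- function(object, newdata, ...) {
  if (is.list(newdata))
    newdata <- vapply(newdata, function(p) p$ratio, numeric(1))
  pmin(pmax(object$intercept + object$slope * newdata,
            object$kappa_range[1]), object$kappa_range[2])
}
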