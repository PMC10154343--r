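#' Construct a feature detector
#'
#' A feature detector (FD) is a spectrotemporal receptive field -- a
#' rectangular patch cut from a cochleagram -- together with the channel
#' span it occupies on the CF grid, a detection threshold on its maximal
#' response, and a log-likelihood voting weight.  The raw sampled patch is
#' stored; normalization is applied at response time so one detector serves
#' every gain-control mode.
#'
#' @param strf time x channel numeric matrix (activation units).
#' @param channel_span integer pair: first and last channel index on the
#'   parent CF grid.
#' @param frame_rate frame rate of the parent cochleagram, Hz.
#' @param threshold detection threshold (correlation units); may be `NA`
#'   before training.
#' @param weight log-likelihood voting weight; may be `NA` before training.
#' @param id opaque identifier.
#' @return An object of class `feature_detector`.
#' @export
feature_detector <- function(strf, channel_span, frame_rate = 1000,
                             threshold = NA_real_, weight = NA_real_,
                             id = NULL) {
  strf <- as.matrix(strf)
  assert_that(is.numeric(strf) && all(is.finite(strf)), "strf must be finite numeric")
  assert_that(length(channel_span) == 2 && channel_span[1] <= channel_span[2],
              "channel_span must be an increasing index pair")
  assert_that(ncol(strf) == channel_span[2] - channel_span[1] + 1,
              "strf channel count must match channel_span")
  structure(list(strf = strf, channel_span = as.integer(channel_span),
                 frame_rate = frame_rate,
                 duration_ms = 1000 * nrow(strf) / frame_rate,
                 threshold = threshold, weight = weight,
                 id = id %||% sprintf("fd_%dx%d", nrow(strf), ncol(strf))),
            class = "feature_detector")
}

#' @export
print.feature_detector <- function(x, ...) {
  cat(sprintf("<feature_detector> %s: %d frames x %d channels (%.0f ms), channels %d-%d, theta=%s, w=%s\n",
              x$id, nrow(x$strf), ncol(x$strf), x$duration_ms,
              x$channel_span[1], x$channel_span[2],
              format(x$threshold, digits = 3), format(x$weight, digits = 3)))
  invisible(x)
}

# template demeaned and scaled to unit population SD; errors on a
# degenerate (constant) patch
normalize_strf <- function(strf) {
  s <- pop_sd(strf)
  if (s <= 0) stop("degenerate feature detector: zero-variance STRF", call. = FALSE)
  (strf - mean(strf)) / s
}

# cochleagram matrix ready for the matching kernel: raw for core and
# cgc_local, globally demeaned / unit-SD for cgc_global
prep_coch_matrix <- function(coch, mode) {
  if (mode != "cgc_global") return(coch$values)
  s <- pop_sd(coch$values)
  if (s <= 0) stop("degenerate input: zero-variance cochleagram", call. = FALSE)
  (coch$values - mean(coch$values)) / s
}

#' Membrane-potential response of a feature detector
#'
#' Sliding cross-correlation of the detector's (demeaned, unit-SD) STRF
#' with the cochleagram, over time only and restricted to the detector's
#' channel span.  Three normalization modes implement increasing degrees of
#' contrast gain control:
#'
#' * `core` -- only the template is normalized; the cochleagram enters raw.
#'   Responses scale with stimulus gain.
#' * `cgc_local` -- each cochleagram window (the boxcar with the
#'   detector's own bandwidth and duration, at every time step) is also
#'   demeaned and scaled to unit SD, so the response is a normalized
#'   correlation in \[-1, 1\].  Zero-variance (silent) windows carry no
#'   feature evidence and score 0; their count is reported.
#' * `cgc_global` -- the whole cochleagram is demeaned and scaled to unit
#'   SD once, then matched as in `core`.
#'
#' Both gain-control modes are invariant to positive-gain and offset
#' transforms of the cochleagram; `core` is not (its response scales with
#' the gain).
#'
#' @param fd a [feature_detector()].
#' @param coch a [compute_cochleagram()] cochleagram whose grid covers the
#'   detector's channel span.
#' @param mode `"core"`, `"cgc_local"`, or `"cgc_global"`.
#' @param pad_short how to treat a cochleagram shorter than the detector:
#'   `"error"` (default) or `"zero"`, which appends silent (zero) frames
#'   until one window fits -- the semantics of a short stimulus embedded in
#'   silence, used throughout training and evaluation where stimulus
#'   durations vary across classes.
#' @return An object of class `vm_response`: list with `values` (one
#'   correlation value per valid onset frame), `mode`, `n_degenerate`.
#' @export
vm_response <- function(fd, coch, mode = c("core", "cgc_local", "cgc_global"),
                        pad_short = c("error", "zero")) {
  mode <- match.arg(mode)
  pad_short <- match.arg(pad_short)
  assert_that(inherits(fd, "feature_detector"), "fd must be a feature_detector")
  assert_that(inherits(coch, "cochleagram"), "coch must be a cochleagram")
  lo <- fd$channel_span[1]; hi <- fd$channel_span[2]
  assert_that(lo >= 1 && hi <= ncol(coch$values),
              "cochleagram does not cover the detector's channel span")
  if (nrow(coch$values) < nrow(fd$strf) && pad_short == "error")
    stop("cochleagram shorter than the detector", call. = FALSE)
  # (with pad_short = "zero" the kernel zero-extends the input itself)
  g <- normalize_strf(fd$strf)
  x <- coch$values[, lo:hi, drop = FALSE]
  if (mode == "cgc_global") {
    mu <- mean(coch$values); s <- pop_sd(coch$values)
    if (s <= 0) stop("degenerate input: zero-variance cochleagram", call. = FALSE)
    x <- (x - mu) / s
  }
  res <- cpp_vm_trace(x, g, if (mode == "cgc_local") 1L else 0L)
  structure(list(values = res$values, mode = mode,
                 n_degenerate = res$n_degenerate),
            class = "vm_response")
}

#' @export
print.vm_response <- function(x, ...) {
  cat(sprintf("<vm_response> mode=%s, %d steps, max=%.4g%s\n", x$mode,
              length(x$values), max(x$values),
              if (x$n_degenerate > 0)
                sprintf(" (%d degenerate windows)", x$n_degenerate) else ""))
  invisible(x)
}

#' Binary detection output of a feature detector
#'
#' Returns 1 iff the maximum of the membrane-potential response reaches the
#' (scaled) threshold: `max Vm >= kappa * threshold`.  The boundary is
#' inclusive.  `kappa` is the top-down excitability scale; `kappa < 1`
#' lowers the effective threshold (greater excitability).
#'
#' @inheritParams vm_response
#' @param kappa positive threshold scale (default 1).
#' @return Integer 0 or 1.
#' @export
fd_detect <- function(fd, coch, mode = "core", kappa = 1) {
  assert_that(is_scalar_number(kappa) && kappa > 0, "kappa must be positive")
  assert_that(is.finite(fd$threshold), "feature detector has no trained threshold")
  vm <- vm_response(fd, coch, mode, pad_short = "zero")
  as.integer(max(vm$values) >= kappa * fd$threshold)
}

#' Descriptive properties of a feature detector
#'
#' Duration from the STRF time extent; center frequency as the geometric
#' mean of the span's edge CFs; bandwidth as `log2(f_hi / f_lo)` octaves;
#' and reduced kurtosis (kurtosis minus 3, with kurtosis the fourth central
#' moment over the fourth power of the SD) computed over all STRF entries
#' as a measure of the patch's tailedness.
#'
#' @param fd a [feature_detector()].
#' @param grid the parent [make_cf_grid()] grid.
#' @return A one-row `data.frame` with columns `duration_ms`,
#'   `center_frequency_hz`, `bandwidth_oct`, `threshold`,
#'   `reduced_kurtosis` (`NA` with a warning for a zero-variance STRF).
#' @export
fd_properties <- function(fd, grid) {
  assert_that(inherits(grid, "cf_grid"), "grid must be a cf_grid")
  f_lo <- grid$frequencies[fd$channel_span[1]]
  f_hi <- grid$frequencies[fd$channel_span[2]]
  v <- as.numeric(fd$strf)
  s <- pop_sd(v)
  rk <- if (s <= 0) {
    warning("zero-variance STRF: reduced kurtosis undefined")
    NA_real_
  } else {
    mean((v - mean(v))^4) / s^4 - 3
  }
  data.frame(duration_ms = fd$duration_ms,
             center_frequency_hz = sqrt(f_lo * f_hi),
             bandwidth_oct = log2(f_hi / f_lo),
             threshold = fd$threshold,
             reduced_kurtosis = rk)
}
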