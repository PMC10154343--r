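#' Log-spaced grid of filter center frequencies
#'
#' Center frequencies are `f_min * 2^(k * step_octaves)` for
#' `k = 0, 1, ...` while the value stays at or below `f_max`.  The default
#' analysis grid of the model spans 200 Hz to 20 kHz in 0.1-octave steps.
#'
#' @param f_min,f_max frequency span in Hz (`0 < f_min <= f_max`).
#' @param step_octaves spacing between adjacent center frequencies, in
#'   octaves (> 0).
#' @return An object of class `cf_grid`: a list with `frequencies` (Hz,
#'   strictly increasing) and `step_octaves`.
#' @examples
#' make_cf_grid(200, 400, 1)     # 200, 400
#' length(make_cf_grid(200, 20000, 0.1)$frequencies)
#' @export
make_cf_grid <- function(f_min = 200, f_max = 20000, step_octaves = 0.1) {
  assert_that(is_scalar_number(f_min) && f_min > 0, "f_min must be positive")
  assert_that(is_scalar_number(f_max) && f_max >= f_min, "f_max must be >= f_min")
  assert_that(is_scalar_number(step_octaves) && step_octaves > 0,
              "step_octaves must be positive")
  n <- floor(log2(f_max / f_min) / step_octaves + 1e-9) + 1
  structure(list(frequencies = f_min * 2^((seq_len(n) - 1) * step_octaves),
                 step_octaves = step_octaves),
            class = "cf_grid")
}

#' @export
print.cf_grid <- function(x, ...) {
  f <- x$frequencies
  cat(sprintf("<cf_grid> %d channels, %.4g-%.4g Hz, %.3g-octave steps\n",
              length(f), min(f), max(f), x$step_octaves))
  invisible(x)
}

#' Front-end configuration
#'
#' Parameters of the default filterbank front-end: gammatone-shaped
#' magnitude responses applied in the frequency domain, half-wave
#' rectification, boxcar envelope smoothing, decimation to the cochleagram
#' frame rate, and optional power-law compression emulating saturating
#' hair-cell transduction.
#'
#' @param frame_rate cochleagram frame rate in Hz (default 1000).
#' @param filter_bw_oct 3-dB bandwidth of each channel filter, in octaves.
#' @param filter_order order of the gammatone-style magnitude response
#'   `(1 + ((f - cf)/b)^2)^(-order/2)`.
#' @param env_cutoff_hz envelope smoothing cutoff; the rectified output is
#'   averaged over a boxcar of `sample_rate / env_cutoff_hz` samples.
#' @param compression_exponent pointwise power-law exponent applied to the
#'   nonnegative envelope (default 0.3); `NULL` disables compression.
#' @return A list of class `frontend_config`.
#' @export
frontend_config <- function(frame_rate = 1000, filter_bw_oct = 0.35,
                            filter_order = 4, env_cutoff_hz = 30,
                            compression_exponent = 0.3) {
  assert_that(frame_rate > 0 && filter_bw_oct > 0 && filter_order > 0 &&
                env_cutoff_hz > 0, "front-end parameters must be positive")
  structure(list(frame_rate = frame_rate, filter_bw_oct = filter_bw_oct,
                 filter_order = filter_order, env_cutoff_hz = env_cutoff_hz,
                 compression_exponent = compression_exponent),
            class = "frontend_config")
}

#' Compute a cochleagram
#'
#' Converts a calibrated waveform into the dense spectrotemporal
#' representation feeding the feature detectors: one nonnegative activation
#' channel per center frequency, sampled at the configured frame rate
#' (1 kHz by default).  Each channel is the signal filtered by a
#' gammatone-shaped bandpass magnitude response (applied by FFT, zero
#' phase), half-wave rectified, envelope-smoothed and decimated; an
#' optional compressive nonlinearity is applied pointwise.
#'
#' Filter group delay is not compensated (the zero-phase filters have
#' none); edge frames are affected by the smoothing window being clipped at
#' the signal boundaries, so shift-based comparisons should use interior
#' frames.
#'
#' @param signal an [audio_signal()] whose sample rate is an integer
#'   multiple of `config$frame_rate`.
#' @param grid a [make_cf_grid()] grid.
#' @param config a [frontend_config()].
#' @return An object of class `cochleagram`: list with `values`
#'   (frames x channels matrix, nonnegative), `frame_rate`, and `grid`.
#' @export
compute_cochleagram <- function(signal, grid = make_cf_grid(),
                                config = frontend_config()) {
  assert_that(inherits(signal, "audio_signal"), "signal must be an audio_signal")
  assert_that(inherits(grid, "cf_grid"), "grid must be a cf_grid")
  fs <- signal$sample_rate
  fr <- config$frame_rate
  assert_that(abs(fs / fr - round(fs / fr)) < 1e-9,
              "sample rate must be an integer multiple of the frame rate")
  dec <- as.integer(round(fs / fr))
  x <- signal$samples
  n <- length(x)
  n_frames <- n %/% dec
  if (n_frames < 1) stop("signal shorter than one cochleagram frame", call. = FALSE)
  cfs <- grid$frequencies
  assert_that(max(cfs) <= fs / 2, "grid extends beyond the Nyquist frequency")

  # frequency-domain filtering with generous zero padding so the circular
  # wrap-around of the (rapidly decaying) filter responses is negligible
  pad <- max(4096L, as.integer(fs %/% 4))
  np <- stats::nextn(n + pad, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(np - n)))
  f_abs <- (0:(np - 1)) / np * fs
  f_abs <- pmin(f_abs, fs - f_abs)

  # window geometry for envelope smoothing + decimation (frame k averages a
  # boxcar centred on that frame's time)
  w <- max(1L, as.integer(round(fs / config$env_cutoff_hz)))
  centre <- as.integer(round((seq_len(n_frames) - 0.5) * dec))
  lo <- pmax(1L, centre - w %/% 2L)
  hi <- pmin(n, lo + w - 1L)
  cnt <- hi - lo + 1

  # -3 dB point of the order-m magnitude response in units of b
  u3 <- sqrt(2^(2 / config$filter_order) - 1)
  vals <- matrix(0, n_frames, length(cfs))
  for (j in seq_along(cfs)) {
    cf <- cfs[j]
    half_bw_hz <- cf * (2^(config$filter_bw_oct / 2) - 2^(-config$filter_bw_oct / 2)) / 2
    b <- half_bw_hz / u3
    H <- (1 + ((f_abs - cf) / b)^2)^(-config$filter_order / 2)
    # equal-noise-gain (unit-energy) scaling: without it the constant-Q
    # bandwidth growth makes white noise drive high-CF channels harder,
    # imprinting a spurious spectral ramp on broadband inputs
    H <- H / sqrt(mean(H^2) * np)
    y <- Re(stats::fft(X * H, inverse = TRUE)) / np
    r <- pmax(y[seq_len(n)], 0)
    cs <- c(0, cumsum(r))
    vals[, j] <- (cs[hi + 1] - cs[lo]) / cnt
  }
  if (!is.null(config$compression_exponent))
    vals <- vals^config$compression_exponent
  structure(list(values = vals, frame_rate = fr, grid = grid),
            class = "cochleagram")
}

#' @export
print.cochleagram <- function(x, ...) {
  cat(sprintf("<cochleagram> %d frames x %d channels @ %g Hz (%.4g-%.4g Hz)\n",
              nrow(x$values), ncol(x$values), x$frame_rate,
              min(x$grid$frequencies), max(x$grid$frequencies)))
  invisible(x)
}

#' @export
plot.cochleagram <- function(x, ...) {
  t <- (seq_len(nrow(x$values)) - 0.5) / x$frame_rate
  graphics::image(t, log2(x$grid$frequencies), x$values,
                  xlab = "Time (s)", ylab = "CF (log2 Hz)",
                  main = "Cochleagram", ...)
  invisible(x)
}

#' Write / read a cochleagram
#'
#' On-disk layout: `<path>.csv` holds the frames-by-channels activation
#' matrix (no header), `<path>.json` is a sidecar with the frame rate and
#' CF grid.
#'
#' @param coch a `cochleagram`.
#' @param path path prefix (without extension).
#' @return `write_cochleagram` returns `path` invisibly;
#'   `read_cochleagram` returns the `cochleagram`.
#' @export
write_cochleagram <- function(coch, path) {
  utils::write.table(coch$values, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(frame_rate = coch$frame_rate,
               cf_hz = coch$grid$frequencies,
               step_octaves = coch$grid$step_octaves)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cochleagram
#' @export
read_cochleagram <- function(path) {
  vals <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- structure(list(frequencies = meta$cf_hz,
                         step_octaves = meta$step_octaves),
                    class = "cf_grid")
  structure(list(values = vals, frame_rate = meta$frame_rate, grid = grid),
            class = "cochleagram")
}

#' Build a cochleagram from a matrix
#'
#' Wraps an existing frames-by-channels activation matrix as a
#' `cochleagram`, attaching a frame rate and CF grid.  Mostly useful for
#' constructing small synthetic inputs.
#'
#' @param values frames x channels numeric matrix.
#' @param frame_rate frame rate in Hz.
#' @param grid a [make_cf_grid()] grid with `ncol(values)` channels; by
#'   default a 0.1-octave grid starting at 200 Hz.
#' @return A `cochleagram`.
#' @export
as_cochleagram <- function(values, frame_rate = 1000,
                           grid = make_cf_grid(200, 200 * 2^(0.1 * (ncol(values) - 1)), 0.1)) {
  structure(list(values = values, frame_rate = frame_rate, grid = grid),
            class = "cochleagram")
}
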