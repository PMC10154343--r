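#' Construct an audio signal
#'
#' A lightweight container for a mono waveform: a numeric sample vector
#' (a dimensionless pressure proxy), a sample rate, and an optional
#' presentation-level tag in dB SPL recording what the signal was last
#' calibrated to.
#'
#' @param samples numeric vector of finite samples.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param level_db_spl optional presentation level in dB SPL; set by
#'   [calibrate_level()].
#' @return An object of class `audio_signal`.
#' @seealso [calibrate_level()], [read_wav()], [write_wav()]
#' @export
audio_signal <- function(samples, sample_rate, level_db_spl = NA_real_) {
  assert_that(is.numeric(samples) && length(samples) > 0, "samples must be a non-empty numeric vector")
  assert_that(all(is.finite(samples)), "samples must be finite")
  assert_that(is_scalar_number(sample_rate) && sample_rate > 0, "sample_rate must be a positive number")
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         level_db_spl = level_db_spl),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.1f ms)",
              length(x$samples), x$sample_rate,
              1000 * length(x$samples) / x$sample_rate))
  if (!is.na(x$level_db_spl)) cat(sprintf(", %.1f dB SPL", x$level_db_spl))
  cat("\n")
  invisible(x)
}

#' Root-mean-square amplitude of a signal
#'
#' @param signal an [audio_signal()] or numeric vector.
#' @return RMS amplitude (scalar).
#' @export
signal_rms <- function(signal) {
  x <- if (inherits(signal, "audio_signal")) signal$samples else signal
  sqrt(mean(x^2))
}

#' Reference pressure used by the SPL calibration convention
#'
#' The package uses the usual 20 micropascal reference: a signal calibrated
#' to `L` dB SPL has RMS amplitude `20e-6 * 10^(L/20)` in the pressure-proxy
#' units of the sample vector.  Absolute SPL realism is not claimed -- only
#' that all stimuli share one consistent level convention, which is all the
#' model's relative comparisons require.
#' @export
SPL_REFERENCE <- 20e-6

#' Calibrate a signal to a target presentation level
#'
#' Rescales the waveform so its RMS corresponds to `target_db_spl` under the
#' [SPL_REFERENCE] convention.  The waveform shape is unchanged up to a
#' positive scalar gain, so calibration is idempotent and invariant to the
#' input's prior scale.
#'
#' @param signal an [audio_signal()].
#' @param target_db_spl target level in dB SPL (default 65, the presentation
#'   level used for all clean and degraded stimuli).
#' @return The calibrated `audio_signal`, with `level_db_spl` set.
#' @export
calibrate_level <- function(signal, target_db_spl = 65) {
  assert_that(inherits(signal, "audio_signal"), "signal must be an audio_signal")
  r <- signal_rms(signal)
  if (r <= 0) stop("cannot calibrate an all-zero signal", call. = FALSE)
  target_rms <- SPL_REFERENCE * 10^(target_db_spl / 20)
  audio_signal(signal$samples * (target_rms / r), signal$sample_rate,
               level_db_spl = target_db_spl)
}

# linear-interpolation resampling; used to bring impulse responses onto a
# signal's sample rate before convolution
resample_linear <- function(samples, from_rate, to_rate) {
  if (from_rate == to_rate) return(samples)
  n_out <- max(2L, round(length(samples) * to_rate / from_rate))
  t_out <- (seq_len(n_out) - 1) / to_rate
  t_in <- (seq_along(samples) - 1) / from_rate
  stats::approx(t_in, samples, xout = pmin(t_out, max(t_in)))$y
}
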