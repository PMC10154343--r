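#' Add white Gaussian noise at a fixed SNR
#'
#' Mixes the signal with white Gaussian noise scaled analytically so that
#' `10 * log10(P_signal / P_noise)` equals `snr_db` exactly, with powers
#' measured as mean squares over the call's full duration (the noise spans
#' exactly the call, with no padding).  `snr_db = Inf` returns the input
#' unchanged.
#'
#' @param signal an [audio_signal()] with nonzero RMS.
#' @param snr_db signal-to-noise ratio in dB (finite or `Inf`).
#' @param rng_seed integer seed; the noise draw is reproducible.
#' @param return_components if `TRUE`, also return the signal and scaled
#'   noise components of the mixture.
#' @return The mixture `audio_signal` (carrying the input's level tag but
#'   not re-calibrated; see [degrade_corpus()] for level handling), or a
#'   list `(mixture, signal, noise)` when `return_components = TRUE`.
#' @export
add_noise_at_snr <- function(signal, snr_db, rng_seed = 1L,
                             return_components = FALSE) {
  assert_that(inherits(signal, "audio_signal"), "signal must be an audio_signal")
  assert_that(is.numeric(snr_db) && length(snr_db) == 1L && !is.na(snr_db),
              "snr_db must be a single non-missing number (may be Inf)")
  if (is.infinite(snr_db) && snr_db > 0) {
    if (return_components)
      return(list(mixture = signal, signal = signal,
                  noise = audio_signal(rep(1e-300, length(signal$samples)),
                                       signal$sample_rate)))
    return(signal)
  }
  p_sig <- mean(signal$samples^2)
  assert_that(p_sig > 0, "signal must be non-silent")
  set.seed(as.integer(rng_seed))
  raw <- stats::rnorm(length(signal$samples))
  gain <- sqrt(p_sig * 10^(-snr_db / 10) / mean(raw^2))
  noise <- raw * gain
  mix <- audio_signal(signal$samples + noise, signal$sample_rate,
                      level_db_spl = signal$level_db_spl)
  if (return_components)
    list(mixture = mix,
         signal = signal,
         noise = audio_signal(noise, signal$sample_rate))
  else mix
}

#' Construct an impulse response
#'
#' @param samples numeric impulse-response samples with finite energy.
#' @param sample_rate sampling rate in Hz.
#' @param t30_ms optional known/estimated T30 in ms.
#' @return An object of class `impulse_response`.
#' @export
impulse_response <- function(samples, sample_rate, t30_ms = NA_real_) {
  assert_that(is.numeric(samples) && length(samples) > 0 && all(is.finite(samples)),
              "impulse response must be a non-empty finite numeric vector")
  assert_that(sum(samples^2) > 0, "impulse response must have positive energy")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 t30_ms = t30_ms),
            class = "impulse_response")
}

#' Apply reverberation by convolution with an impulse response
#'
#' Full linear convolution of the call with the impulse response (output
#' length `length(signal) + length(ir) - 1`), followed by re-calibration to
#' the configured presentation level, so clean and reverberant stimuli are
#' presented at the same level.  If the sample rates differ the impulse
#' response is resampled by linear interpolation.
#'
#' @param signal an [audio_signal()].
#' @param ir an [impulse_response()].
#' @param level_db_spl presentation level of the output; defaults to the
#'   signal's calibrated level, or 65 dB SPL if the signal carries none.
#' @return The reverberant `audio_signal`.
#' @export
apply_reverb <- function(signal, ir, level_db_spl = NULL) {
  assert_that(inherits(signal, "audio_signal"), "signal must be an audio_signal")
  assert_that(inherits(ir, "impulse_response"), "ir must be an impulse_response")
  h <- ir$samples
  if (ir$sample_rate != signal$sample_rate)
    h <- resample_linear(h, ir$sample_rate, signal$sample_rate)
  x <- signal$samples
  n_out <- length(x) + length(h) - 1
  np <- stats::nextn(n_out, c(2, 3, 5))
  y <- Re(stats::fft(stats::fft(c(x, numeric(np - length(x)))) *
                       stats::fft(c(h, numeric(np - length(h)))),
                     inverse = TRUE)) / np
  out <- audio_signal(y[seq_len(n_out)], signal$sample_rate)
  lvl <- level_db_spl %||% (if (is.na(signal$level_db_spl)) 65 else signal$level_db_spl)
  calibrate_level(out, lvl)
}

#' Estimate reverberation strength (T30) of an impulse response
#'
#' Computes the Schroeder backward-integrated energy decay curve, fits a
#' least-squares line to it over the 0 to -30 dB span (excluding the final
#' 10% of the impulse response, where the backward integral is biased by
#' truncation), and reports the time for the fitted decay to fall 30 dB.
#' The estimate is invariant to the amplitude scale of the impulse
#' response.
#'
#' @param ir an [impulse_response()].
#' @return T30 in ms.  If the decay curve never reaches -30 dB within the
#'   fit span, the impulse-response duration is returned as a flagged upper
#'   bound (attribute `censored = TRUE`) with a warning.
#' @export
estimate_t30 <- function(ir) {
  assert_that(inherits(ir, "impulse_response"), "ir must be an impulse_response")
  h <- ir$samples
  fs <- ir$sample_rate
  edc <- rev(cumsum(rev(h^2)))
  n <- length(h)
  dur_ms <- 1000 * n / fs
  if (n < 2) return(structure(dur_ms, censored = FALSE))
  level <- 10 * log10(edc / edc[1])
  keep <- seq_len(max(2L, floor(0.9 * n)))          # drop truncation tail
  span <- keep[level[keep] >= -30]
  if (length(span) < 2 || min(level[keep]) > -30 + 1e-12) {
    warning("decay curve does not reach -30 dB; returning IR duration as an upper bound")
    return(structure(dur_ms, censored = TRUE))
  }
  t_ms <- (span - 1) / fs * 1000
  fit <- stats::lm.fit(cbind(1, t_ms), level[span])
  slope <- fit$coefficients[2]                       # dB per ms
  if (!is.finite(slope) || slope >= 0) {
    warning("non-decaying energy curve; returning IR duration as an upper bound")
    return(structure(dur_ms, censored = TRUE))
  }
  structure(as.numeric(-30 / slope), censored = FALSE)
}

#' Synthesize an impulse response with a target T30
#'
#' Gaussian noise shaped by an exponential amplitude envelope
#' `exp(-t * log(10^(30/20)) / t30)`, so the energy envelope decays by
#' 30 dB over `t30_target` ms.  A stand-in for recorded or room-simulated
#' impulse responses, with the reverberation strength as the single knob.
#'
#' @param t30_target target T30 in ms (> 0).
#' @param duration_ms impulse-response duration; must be at least
#'   `2 * t30_target` (default `2.5 * t30_target`).
#' @param sample_rate sampling rate in Hz.
#' @param rng_seed integer seed; same seed gives a bit-identical response.
#' @return An [impulse_response()] with `t30_ms` set to the target.
#' @export
synth_impulse_response <- function(t30_target, duration_ms = 2.5 * t30_target,
                                   sample_rate = 16000, rng_seed = 1L) {
  assert_that(is_scalar_number(t30_target) && t30_target > 0,
              "t30_target must be positive")
  assert_that(duration_ms >= 2 * t30_target,
              "duration_ms must be at least 2 * t30_target")
  n <- max(8L, as.integer(round(duration_ms / 1000 * sample_rate)))
  t_ms <- (seq_len(n) - 1) / sample_rate * 1000
  env <- exp(-t_ms * log(10^(30 / 20)) / t30_target)
  set.seed(as.integer(rng_seed))
  impulse_response(stats::rnorm(n) * env, sample_rate, t30_ms = t30_target)
}
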