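#' Specification of a synthetic call class
#'
#' Describes one vocalization category for the generator.  Four syllable
#' kinds cover the archetypal spectrotemporal structures of rodent and
#' primate call repertoires: a harmonic tonal call, a single frequency
#' sweep (linear in log-frequency), a train of repeated short FM syllables
#' separated by gaps, and amplitude-modulated band-limited noise.
#' Per-call production variability is emulated by multiplicative lognormal
#' jitter applied to every drawn parameter.
#'
#' @param name class label.
#' @param kind one of `"tonal"`, `"fm_sweep"`, `"repeated_fm"`, `"am_noise"`.
#' @param f0_range fundamental (or lower band edge for `am_noise`) range, Hz.
#' @param duration_range_ms call duration range, ms (for `repeated_fm` the
#'   duration emerges from the syllable train and this range is ignored).
#' @param harmonics number of harmonics of the F0 trajectory (tonal / FM
#'   kinds); amplitudes fall off as 1/h.
#' @param sweep_rate_range_oct sweep rate range in octaves/s (`fm_sweep`).
#' @param am_rate_range_hz amplitude-modulation rate range, Hz (`am_noise`).
#' @param band_oct noise bandwidth above the lower edge, octaves (`am_noise`).
#' @param n_syllables_range syllable-count range (`repeated_fm`).
#' @param syllable_ms_range,gap_ms_range syllable and gap duration ranges,
#'   ms (`repeated_fm`).
#' @param syllable_oct octaves swept within one repeated-FM syllable.
#' @param jitter relative SD of the lognormal production jitter (default
#'   0.15).
#' @return A list of class `call_class_spec`.
#' @export
call_class_spec <- function(name, kind, f0_range, duration_range_ms,
                            harmonics = 1L, sweep_rate_range_oct = NULL,
                            am_rate_range_hz = NULL, band_oct = 1.5,
                            n_syllables_range = NULL,
                            syllable_ms_range = c(35, 50),
                            gap_ms_range = c(20, 35),
                            syllable_oct = 0.8, jitter = 0.15) {
  kind <- match.arg(kind, c("tonal", "fm_sweep", "repeated_fm", "am_noise"))
  assert_that(length(f0_range) == 2 && all(f0_range > 0) && diff(f0_range) >= 0,
              "f0_range must be a non-decreasing positive pair")
  assert_that(all(duration_range_ms > 0), "durations must be positive")
  structure(list(name = name, kind = kind, f0_range = f0_range,
                 duration_range_ms = duration_range_ms,
                 harmonics = as.integer(harmonics),
                 sweep_rate_range_oct = sweep_rate_range_oct,
                 am_rate_range_hz = am_rate_range_hz, band_oct = band_oct,
                 n_syllables_range = n_syllables_range,
                 syllable_ms_range = syllable_ms_range,
                 gap_ms_range = gap_ms_range, syllable_oct = syllable_oct,
                 jitter = jitter),
            class = "call_class_spec")
}

#' Default synthetic call classes
#'
#' Four categories spanning the archetypes that make categorization under
#' degradation interesting: `chut` (short rising low-frequency sweep),
#' `wheek` (long high-frequency tonal call with a slow upward drift),
#' `rumble` (low-frequency amplitude-modulated noise), and `whine` (a
#' train of fast FM syllables -- the class whose short-time-scale structure
#' reverberation smears most).
#'
#' @param jitter relative production-variability SD shared by all classes.
#' @return Named list of [call_class_spec()] objects.
#' @export
default_call_classes <- function(jitter = 0.15) {
  list(
    chut = call_class_spec("chut", "fm_sweep", f0_range = c(350, 550),
                           duration_range_ms = c(150, 250), harmonics = 2L,
                           sweep_rate_range_oct = c(3, 5), jitter = jitter),
    wheek = call_class_spec("wheek", "tonal", f0_range = c(2200, 3000),
                            duration_range_ms = c(400, 600), harmonics = 2L,
                            jitter = jitter),
    rumble = call_class_spec("rumble", "am_noise", f0_range = c(300, 450),
                             duration_range_ms = c(350, 550),
                             am_rate_range_hz = c(10, 16), band_oct = 1.5,
                             jitter = jitter),
    whine = call_class_spec("whine", "repeated_fm", f0_range = c(900, 1300),
                            duration_range_ms = c(300, 500), harmonics = 1L,
                            n_syllables_range = c(5, 8), jitter = jitter)
  )
}

# draw uniformly within a range, then apply lognormal production jitter
draw_param <- function(range, jitter) {
  v <- stats::runif(1, range[1], range[2])
  if (jitter > 0) v <- v * exp(jitter * stats::rnorm(1))
  v
}

cos_ramp <- function(n, fs, ramp_ms = 5) {
  nr <- min(n %/% 2, max(1L, round(ramp_ms / 1000 * fs)))
  r <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  c(r, rep(1, n - 2 * nr), rev(r))
}

harmonic_stack <- function(f_traj, fs, harmonics) {
  phase <- 2 * pi * cumsum(f_traj) / fs
  x <- numeric(length(f_traj))
  for (h in seq_len(harmonics)) {
    f_h <- f_traj * h
    keep <- max(f_h) < 0.45 * fs
    if (keep) x <- x + sin(phase * h) / h
  }
  x
}

# FFT band-pass with raised-cosine edges (widths in octaves)
bandpass_noise <- function(n, fs, f_lo, f_hi, edge_oct = 0.15) {
  np <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(stats::rnorm(n), numeric(np - n)))
  f <- (0:(np - 1)) / np * fs
  f <- pmin(f, fs - f)
  g <- numeric(np)
  inside <- f >= f_lo & f <= f_hi
  g[inside] <- 1
  lo_edge <- f > f_lo * 2^(-edge_oct) & f < f_lo
  g[lo_edge] <- 0.5 * (1 - cos(pi * log2(f[lo_edge] / (f_lo * 2^(-edge_oct))) / edge_oct))
  hi_edge <- f > f_hi & f < f_hi * 2^(edge_oct)
  g[hi_edge] <- 0.5 * (1 + cos(pi * log2(f[hi_edge] / f_hi) / edge_oct))
  Re(stats::fft(X * g, inverse = TRUE))[seq_len(n)] / np
}

#' Synthesize one call
#'
#' Draws production parameters within the class ranges (with lognormal
#' jitter), synthesizes the waveform for the class's syllable kind, applies
#' 5-ms cosine onset/offset ramps, and calibrates the result to the
#' presentation level.
#'
#' @param spec a [call_class_spec()].
#' @param rng_seed integer seed (same seed, same call).
#' @param sample_rate output sampling rate, Hz.
#' @param level_db_spl presentation level (default 65 dB SPL).
#' @return An [audio_signal()] with attribute `label` set to the class name.
#' @export
synth_call <- function(spec, rng_seed = 1L, sample_rate = 16000,
                       level_db_spl = 65) {
  assert_that(inherits(spec, "call_class_spec"), "spec must be a call_class_spec")
  fs <- sample_rate
  set.seed(as.integer(rng_seed))
  j <- spec$jitter
  x <- switch(
    spec$kind,
    tonal = {
      dur <- draw_param(spec$duration_range_ms, j) / 1000
      f0 <- draw_param(spec$f0_range, j)
      n <- max(16L, round(dur * fs))
      tt <- (seq_len(n) - 1) / fs
      # slow upward drift plus a gentle wobble, in octaves
      drift <- 0.15 * exp(j * stats::rnorm(1))
      f_traj <- f0 * 2^(drift * tt / dur + 0.03 * sin(2 * pi * 2.5 * tt))
      harmonic_stack(f_traj, fs, spec$harmonics)
    },
    fm_sweep = {
      dur <- draw_param(spec$duration_range_ms, j) / 1000
      f0 <- draw_param(spec$f0_range, j)
      rate <- draw_param(spec$sweep_rate_range_oct, j)
      n <- max(16L, round(dur * fs))
      tt <- (seq_len(n) - 1) / fs
      f_traj <- f0 * 2^(rate * tt)
      harmonic_stack(f_traj, fs, spec$harmonics)
    },
    repeated_fm = {
      n_syl <- max(2L, round(draw_param(spec$n_syllables_range, j)))
      pieces <- list()
      for (s in seq_len(n_syl)) {
        syl_ms <- draw_param(spec$syllable_ms_range, j)
        gap_ms <- draw_param(spec$gap_ms_range, j)
        f0 <- draw_param(spec$f0_range, j)
        ns <- max(16L, round(syl_ms / 1000 * fs))
        tt <- (seq_len(ns) - 1) / fs
        f_traj <- f0 * 2^(spec$syllable_oct * tt / (syl_ms / 1000))
        syl <- harmonic_stack(f_traj, fs, spec$harmonics) * cos_ramp(ns, fs, 2)
        pieces[[s]] <- c(syl, numeric(round(gap_ms / 1000 * fs)))
      }
      unlist(pieces)
    },
    am_noise = {
      dur <- draw_param(spec$duration_range_ms, j) / 1000
      f_lo <- draw_param(spec$f0_range, j)
      am <- draw_param(spec$am_rate_range_hz, j)
      n <- max(32L, round(dur * fs))
      tt <- (seq_len(n) - 1) / fs
      carrier <- bandpass_noise(n, fs, f_lo, f_lo * 2^spec$band_oct)
      env <- 0.05 + 0.95 * 0.5 * (1 - cos(2 * pi * am * tt))
      carrier * env
    }
  )
  x <- x * cos_ramp(length(x), fs)
  if (all(x == 0)) x[1] <- 1e-12
  out <- calibrate_level(audio_signal(x, fs), level_db_spl)
  attr(out, "label") <- spec$name
  out
}

#' Generate a labeled synthetic corpus
#'
#' Balanced corpus of `n_per_class` calls for each class, fully
#' reproducible from `rng_seed`.
#'
#' @param specs named list of [call_class_spec()] (default
#'   [default_call_classes()]).
#' @param n_per_class calls per class.
#' @param rng_seed integer seed.
#' @param sample_rate sampling rate, Hz.
#' @return An object of class `call_corpus`: list with `calls` (list of
#'   [audio_signal()]), `labels` (character), `class_specs`, `rng_seed`.
#' @export
make_corpus <- function(specs = default_call_classes(), n_per_class = 10,
                        rng_seed = 1L, sample_rate = 16000) {
  assert_that(n_per_class > 0, "n_per_class must be positive")
  calls <- list(); labels <- character(0)
  k <- 0L
  for (ci in seq_along(specs)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      calls[[k]] <- synth_call(specs[[ci]],
                               rng_seed = derive_seed(rng_seed, ci * 1000L + i),
                               sample_rate = sample_rate)
      labels[k] <- specs[[ci]]$name
    }
  }
  structure(list(calls = calls, labels = labels, class_specs = specs,
                 rng_seed = rng_seed),
            class = "call_corpus")
}

#' @export
print.call_corpus <- function(x, ...) {
  cat(sprintf("<call_corpus> %d calls, classes: %s\n", length(x$calls),
              paste(sprintf("%s (%d)", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

#' Stratified train/test split of a corpus
#'
#' @param corpus a [make_corpus()] corpus.
#' @param train_frac fraction of each class assigned to training.
#' @param rng_seed integer seed for the stratified draw.
#' @return List with `train` and `test` corpora (disjoint calls).
#' @export
split_corpus <- function(corpus, train_frac = 0.5, rng_seed = 1L) {
  set.seed(as.integer(rng_seed))
  idx_train <- integer(0)
  for (cl in unique(corpus$labels)) {
    ii <- which(corpus$labels == cl)
    idx_train <- c(idx_train, sort(sample(ii, round(train_frac * length(ii)))))
  }
  idx_test <- setdiff(seq_along(corpus$calls), idx_train)
  subset_corpus <- function(idx) {
    structure(list(calls = corpus$calls[idx], labels = corpus$labels[idx],
                   class_specs = corpus$class_specs, rng_seed = corpus$rng_seed),
              class = "call_corpus")
  }
  list(train = subset_corpus(idx_train), test = subset_corpus(idx_test))
}

#' Degrade every call in a corpus
#'
#' Applies one degradation -- additive white noise at a fixed SNR or
#' reverberation with a given impulse response -- to every call, then
#' re-calibrates each degraded call to the presentation level (both clean
#' and degraded stimuli are presented at the same level).
#'
#' @param corpus a `call_corpus`.
#' @param snr_db SNR in dB (use `Inf` or leave `ir` unset for clean).
#' @param ir an [impulse_response()] for reverberation.
#' @param rng_seed integer seed for the per-call noise draws.
#' @param level_db_spl presentation level of the degraded calls.
#' @return The degraded `call_corpus`.
#' @export
degrade_corpus <- function(corpus, snr_db = Inf, ir = NULL, rng_seed = 1L,
                           level_db_spl = 65) {
  calls <- corpus$calls
  for (i in seq_along(calls)) {
    x <- calls[[i]]
    if (!is.null(ir)) {
      x <- apply_reverb(x, ir, level_db_spl = level_db_spl)
    } else if (is.finite(snr_db)) {
      x <- add_noise_at_snr(x, snr_db, rng_seed = derive_seed(rng_seed, i))
      x <- calibrate_level(x, level_db_spl)
    }
    calls[[i]] <- x
  }
  structure(list(calls = calls, labels = corpus$labels,
                 class_specs = corpus$class_specs, rng_seed = corpus$rng_seed),
            class = "call_corpus")
}

#' Cochleagrams for every call in a corpus
#'
#' @param corpus a `call_corpus`.
#' @param grid a [make_cf_grid()] grid.
#' @param config a [frontend_config()].
#' @return List with `cochleagrams` (list of [compute_cochleagram()]
#'   outputs) and `labels`.
#' @export
corpus_cochleagrams <- function(corpus, grid = make_cf_grid(200, 6400, 0.1),
                                config = frontend_config()) {
  list(cochleagrams = lapply(corpus$calls, compute_cochleagram,
                             grid = grid, config = config),
       labels = corpus$labels)
}
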