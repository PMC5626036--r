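#' Beat morphology parameters for the synthetic ECG generator
#'
#' One heartbeat is modelled as a sum of five Gaussian bumps, one per wave
#' (P, Q, R, S, T), on a zero baseline. Each wave has an amplitude in mV, a
#' center offset in milliseconds relative to the R peak, and a width (Gaussian
#' standard deviation) in milliseconds. Q and S are negative deflections. The
#' defaults give a textbook normal-sinus morphology at 60 bpm in which the R
#' amplitude strictly dominates, so the sample-wise argmax of a clean beat is
#' the R peak — the property the wavelet detector relies on.
#'
#' @param amplitude Named numeric vector of wave amplitudes (mV); names must
#'   be `c("P","Q","R","S","T")`.
#' @param offset_ms Named numeric vector of wave centers relative to R (ms).
#' @param width_ms Named numeric vector of Gaussian widths (ms); all > 0.
#' @param hr Heart rate in beats per minute; fixes the beat duration 60/hr s.
#'
#' @return Object of class `beat_shape_params`.
#' @export
beat_shape_params <- function(amplitude = c(P = 0.12, Q = -0.10, R = 1.00,
                                            S = -0.15, T = 0.30),
                              offset_ms = c(P = -170, Q = -25, R = 0,
                                            S = 30, T = 250),
                              width_ms = c(P = 25, Q = 10, R = 12,
                                           S = 10, T = 60),
                              hr = 60) {
  waves <- c("P", "Q", "R", "S", "T")
  for (v in list(amplitude, offset_ms, width_ms)) {
    if (!identical(sort(names(v)), sort(waves))) {
      stop("wave parameters must be named P, Q, R, S, T", call. = FALSE)
    }
  }
  if (any(width_ms <= 0)) stop("wave widths must be > 0", call. = FALSE)
  if (!is.numeric(hr) || hr <= 0) stop("`hr` must be > 0", call. = FALSE)
  pos <- amplitude[amplitude > 0 & names(amplitude) != "R"]
  if (length(pos) && any(pos >= amplitude[["R"]])) {
    stop("R amplitude must strictly dominate the other positive waves",
         call. = FALSE)
  }
  structure(list(amplitude = amplitude[waves], offset_ms = offset_ms[waves],
                 width_ms = width_ms[waves], hr = hr),
            class = "beat_shape_params")
}

#' Noise parameters for the synthetic ECG generator
#'
#' Additive disturbances layered on the clean concatenated beats: seeded white
#' Gaussian noise and a sinusoidal baseline wander. The default wander
#' frequency sits in the respiratory drift band (0.15–0.3 Hz) that the
#' baseline-removal stage is designed to cancel.
#'
#' @param sd White-noise standard deviation (mV), >= 0.
#' @param wander_amp Baseline-wander amplitude (mV), >= 0.
#' @param wander_freq Baseline-wander frequency (Hz), > 0.
#' @param seed Integer RNG seed; the generator is a pure function of its
#'   arguments including this seed.
#' @param amp_jitter_sd Standard deviation of the per-beat multiplicative
#'   amplitude jitter (0 disables it, the default, so records are exactly
#'   periodic).
#'
#' @return Object of class `noise_params`.
#' @export
noise_params <- function(sd = 0.02, wander_amp = 0.10, wander_freq = 0.20,
                         seed = 1L, amp_jitter_sd = 0) {
  if (sd < 0 || wander_amp < 0 || amp_jitter_sd < 0) {
    stop("noise magnitudes must be >= 0", call. = FALSE)
  }
  if (wander_freq <= 0) stop("`wander_freq` must be > 0", call. = FALSE)
  structure(list(sd = sd, wander_amp = wander_amp, wander_freq = wander_freq,
                 seed = as.integer(seed), amp_jitter_sd = amp_jitter_sd),
            class = "noise_params")
}

#' Generate one clean synthetic heartbeat
#'
#' Deterministically renders a single beat of duration `60/hr` seconds at
#' sampling rate `fs` as the sum of the five Gaussian wave bumps. The R center
#' is placed at 35% of the beat so that the default segmentation window
#' (105 samples before R, 165 after) always fits inside the beat at 360 Hz.
#'
#' @param fs Sampling rate (Hz).
#' @param shape A [beat_shape_params()] object.
#'
#' @return List with `samples` (numeric, length `round(fs * 60 / hr)`),
#'   `r_index` (1-based sample index of the R center), `landmarks` (named
#'   1-based indices of all five wave centers) and `fs`.
#' @examples
#' b <- generate_beat(360, beat_shape_params())
#' which.max(b$samples) == b$r_index
#' @export
generate_beat <- function(fs, shape = beat_shape_params()) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  n <- round(fs * 60 / shape$hr)
  if (n < 271) {
    stop("beat duration 60/hr must span at least 271 samples at `fs`",
         call. = FALSE)
  }
  r_index <- floor(0.35 * n) + 1L
  t_ms <- ((seq_len(n) - r_index) / fs) * 1000
  samples <- numeric(n)
  for (w in names(shape$amplitude)) {
    samples <- samples + shape$amplitude[[w]] *
      exp(-0.5 * ((t_ms - shape$offset_ms[[w]]) / shape$width_ms[[w]])^2)
  }
  landmarks <- r_index + round(shape$offset_ms * fs / 1000)
  names(landmarks) <- names(shape$offset_ms)
  list(samples = samples, r_index = r_index, landmarks = landmarks, fs = fs)
}

#' Generate a synthetic ECG record with known ground truth
#'
#' Concatenates `n_beats` copies of the Gaussian-bump beat, adds a sinusoidal
#' baseline wander and seeded white noise, and returns the noisy record
#' together with the exact R-peak indices and the clean (noise-free) reference
#' signal. Identical arguments — including the seed inside `noise` — always
#' reproduce bit-identical output, so generated records serve as fixtures with
#' exact ground truth for the detector and the distortion metrics.
#'
#' @param fs Sampling rate (Hz); default 360, the rate at which the pipeline's
#'   270-sample beat window corresponds to 0.75 s.
#' @param n_beats Number of beats, >= 1.
#' @param shape A [beat_shape_params()] object.
#' @param noise A [noise_params()] object.
#'
#' @return List with `record` (an [ecg_record()]), `r_peaks` (integer vector,
#'   length `n_beats`, 1-based), and `clean` (numeric vector, the noise-free
#'   concatenated beats).
#' @examples
#' g <- generate_record(fs = 360, n_beats = 3)
#' diff(g$r_peaks)
#' @export
generate_record <- function(fs = 360, n_beats = 10,
                            shape = beat_shape_params(),
                            noise = noise_params()) {
  if (n_beats < 1) stop("`n_beats` must be >= 1", call. = FALSE)
  beat <- generate_beat(fs, shape)
  L <- length(beat$samples)
  n <- L * n_beats
  with_seed(noise$seed, {
    gains <- if (noise$amp_jitter_sd > 0) {
      stats::rnorm(n_beats, mean = 1, sd = noise$amp_jitter_sd)
    } else {
      rep(1, n_beats)
    }
    clean <- as.numeric(vapply(gains, function(g) g * beat$samples,
                               numeric(L)))
    wander <- noise$wander_amp *
      sin(2 * pi * noise$wander_freq * (seq_len(n) - 1L) / fs)
    white <- if (noise$sd > 0) stats::rnorm(n, sd = noise$sd) else numeric(n)
    samples <- clean + wander + white
  })
  r_peaks <- beat$r_index + L * (seq_len(n_beats) - 1L)
  list(record = ecg_record(samples, fs, id = "synthetic"),
       r_peaks = as.integer(r_peaks), clean = clean)
}
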