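## Unvoiced (turbulent) excitation, built directly in the frequency domain:
## per-frame magnitudes are drawn from a uniform distribution, shaped by a
## piecewise spectral slope (flat up to a ceiling frequency, then
## rolloff_noise dB/kHz), multiplied by a vocal-tract transfer function, and
## inverse-STFT'd with overlap-add.

#' Noise-source parameter set
#'
#' @param envelope amplitude envelope of the noise component, anchors in dB
#'   (independent of the voiced envelope; `-Inf` silences the noise).
#' @param rolloff_noise spectral slope above `flat_ceiling`, dB per kHz
#'   (negative = decay; 0 = white up to Nyquist).
#' @param flat_ceiling upper edge of the flat portion of the noise source
#'   spectrum, Hz.
#' @param own_filter optional [formant_table()] used instead of the shared
#'   vocal-tract transfer function, for noises produced away from the
#'   glottis (e.g. hissing).
#' @return an object of class `noise_params`.
#' @export
noise_params <- function(envelope = -Inf, rolloff_noise = -4,
                         flat_ceiling = 1200, own_filter = NULL) {
  stopifnot_scalar(flat_ceiling, "flat_ceiling", lo = 1)
  stopifnot_scalar(rolloff_noise, "rolloff_noise")
  if (!is.null(own_filter)) own_filter <- formant_table(own_filter)
  env <- if (inherits(envelope, "contour_spec")) envelope
  else contour_spec(envelope, scale = "linear", parameter = "noise_env")
  structure(list(envelope = env, rolloff_noise = rolloff_noise,
                 flat_ceiling = flat_ceiling, own_filter = own_filter),
            class = "noise_params")
}

## piecewise source-spectrum gain for the noise component, in dB:
## 0 below the flat ceiling, rolloff_noise dB/kHz above it
noise_rolloff_db <- function(freq, rolloff_noise, flat_ceiling = 1200) {
  ifelse(freq <= flat_ceiling, 0,
         rolloff_noise * (freq - flat_ceiling) / 1000)
}

#' Synthesize the turbulent-noise component
#'
#' Per STFT frame, one-sided spectral magnitudes are drawn i.i.d. uniform on
#' `[0, 1]`, multiplied by the piecewise rolloff gain (flat up to
#' `flat_ceiling`, then `rolloff_noise` dB/kHz) and by the vocal-tract
#' transfer function, given uniform random phases, and converted to a
#' waveform by inverse STFT with overlap-add.  The result is scaled by the
#' noise amplitude envelope (dB) and trimmed to `round(duration *
#' sampling_rate)` samples.
#'
#' @param params a [noise_params()] object.
#' @param duration seconds.
#' @param sampling_rate Hz.
#' @param transfer optional [spectral_envelope()]; when `params$own_filter`
#'   is set it takes precedence (its envelope is computed on the noise's own
#'   frame grid).  NULL means a unity transfer function.
#' @param seed integer seed, or NULL.
#' @return a [waveform()] (not normalized).
#' @export
generate_noise <- function(params, duration, sampling_rate,
                           transfer = NULL, seed = NULL) {
  stopifnot(inherits(params, "noise_params"))
  stopifnot_scalar(duration, "duration", lo = 1e-9)
  stopifnot_scalar(sampling_rate, "sampling_rate", lo = 1)
  n <- as.integer(round(duration * sampling_rate))
  n_frames <- stft_n_frames(n)
  nb <- STFT_N %/% 2L + 1L
  freqs <- stft_bin_freqs(sampling_rate)
  shape <- db_to_lin(noise_rolloff_db(freqs, params$rolloff_noise,
                                      params$flat_ceiling))
  if (!is.null(params$own_filter)) {
    transfer <- compute_spectral_envelope(
      params$own_filter,
      geometry = stft_geometry(sampling_rate, n_frames))
  }
  gain <- NULL
  if (!is.null(transfer)) {
    stopifnot(inherits(transfer, "spectral_envelope"))
    if (nrow(transfer$gain) != nb)
      stop("transfer function bin count does not match the STFT geometry",
           call. = FALSE)
    gain <- transfer$gain
    if (ncol(gain) != n_frames) {
      ## map envelope frames onto noise frames by relative position
      idx <- pmax(1L, pmin(ncol(gain), round(seq(1, ncol(gain),
                                                 length.out = n_frames))))
      gain <- gain[, idx, drop = FALSE]
    }
  }
  S <- with_seed(seed, {
    mag <- matrix(stats::runif(nb * n_frames), nb, n_frames) * shape
    if (!is.null(gain)) mag <- mag * gain
    ph <- matrix(stats::runif(nb * n_frames, 0, 2 * pi), nb, n_frames)
    mag * exp(1i * ph)
  })
  S[1L, ] <- 0          # no DC
  S[nb, ] <- Re(S[nb, ]) # real Nyquist bin
  ## level convention: unity transfer + 0 dB envelope gives RMS ~ 0.3
  sf <- structure(list(S = S * 16, sampling_rate = sampling_rate,
                       n_fft = STFT_N, hop = STFT_HOP, pad = STFT_N,
                       n_samples = n),
                  class = "stft_frames")
  x <- istft(sf)
  env_db <- sample_contour(params$envelope, duration, sampling_rate)$values
  env_db <- env_db[seq_len(min(n, length(env_db)))]
  if (length(env_db) < n)
    env_db <- c(env_db, rep(env_db[length(env_db)], n - length(env_db)))
  waveform(x * db_to_lin(env_db), sampling_rate)
}

#' Mix voiced and unvoiced components
#'
#' Sample-wise sum after placing each component at its onset offset.  Either
#' input may be empty (length 0), which supports purely voiceless synthesis.
#' No normalization or clipping happens here; that is the final assembly
#' step.
#'
#' @param voiced,unvoiced [waveform()] objects sharing a sampling rate.
#' @param alignment numeric length-2: onset offsets (s) of the voiced and
#'   unvoiced components.
#' @return a [waveform()].
#' @export
mix_voiced_unvoiced <- function(voiced, unvoiced, alignment = c(0, 0)) {
  stopifnot(inherits(voiced, "waveform"), inherits(unvoiced, "waveform"))
  if (length(voiced$samples) && length(unvoiced$samples) &&
      voiced$sampling_rate != unvoiced$sampling_rate)
    stop("voiced and unvoiced sampling rates differ", call. = FALSE)
  sr <- if (length(voiced$samples)) voiced$sampling_rate
        else unvoiced$sampling_rate
  off <- as.integer(round(alignment * sr))
  if (any(off < 0)) stop("alignment offsets must be >= 0", call. = FALSE)
  n <- max(off[1L] + length(voiced$samples), off[2L] + length(unvoiced$samples))
  out <- numeric(n)
  if (length(voiced$samples))
    out[off[1L] + seq_along(voiced$samples)] <-
      out[off[1L] + seq_along(voiced$samples)] + voiced$samples
  if (length(unvoiced$samples))
    out[off[2L] + seq_along(unvoiced$samples)] <-
      out[off[2L] + seq_along(unvoiced$samples)] + unvoiced$samples
  waveform(out, sr)
}
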