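## Vocal-tract filter: formants (poles) and antiformants (zeros) define a
## transfer function -- a gain for every STFT bin and frame -- which is
## applied by spectrogram multiplication (STFT, multiply, inverse STFT).
## Formant series derive from vocal-tract length under the uniform-tube
## model: F_n = (2n - 1)/2 * d with dispersion d = c/(2 * VTL), c = 35,400
## cm/s in warm air.

#' Formant table
#'
#' Per-formant time-varying frequency plus optional amplitude, bandwidth and
#' strength; antiformants (spectral zeros, as in nasalization) carry the
#' same fields.
#'
#' @param formants a list of formants, each either a single frequency in Hz,
#'   an anchor list (see [contour_spec()]), or a list with elements `freq`
#'   (required), `amp` (dB, default 0), `width` (Hz, default estimated from
#'   frequency via [estimate_bandwidth()]), and `strength` (exponent on the
#'   resonance term, default 1).  May be an existing `formant_table`.
#' @param antiformants same structure, interpreted as zeros.
#' @return an object of class `formant_table`.
#' @examples
#' ft <- formant_table(list(f1 = 700, f2 = 1200, f3 = 2600))
#' @export
formant_table <- function(formants = list(), antiformants = list()) {
  if (inherits(formants, "formant_table")) return(formants)
  norm1 <- function(f, id) {
    if (is.numeric(f) || is.matrix(f) || (is.list(f) && is.null(f$freq)))
      f <- list(freq = f)
    if (is.null(f$freq)) stop(sprintf("formant '%s' lacks `freq`", id),
                              call. = FALSE)
    list(freq = contour_spec(f$freq, scale = "log", parameter = "formant",
                             range = c(1, 1e6)),
         amp = f$amp %||% 0,
         width = f$width,
         strength = f$strength %||% 1)
  }
  ids <- names(formants) %||%
    as.character(sprintf("f%d", seq_along(formants)))
  aids <- names(antiformants) %||%
    as.character(sprintf("af%d", seq_along(antiformants)))
  structure(list(
    formants = stats::setNames(Map(norm1, formants, as.list(ids)), ids),
    antiformants = stats::setNames(Map(norm1, antiformants, as.list(aids)),
                                   aids)),
    class = "formant_table")
}

#' @export
print.formant_table <- function(x, ...) {
  cat(sprintf("<formant_table: %d formant(s), %d antiformant(s)>\n",
              length(x$formants), length(x$antiformants)))
  invisible(x)
}

#' Vocal-tract geometry and radiation parameters
#'
#' @param vtl vocal-tract length in cm, or NULL to estimate it from the
#'   user's formants.
#' @param mouth mouth-opening contour, values in `[0, 1]` (0 = closed, 1 =
#'   fully open, 0.5 = neutral).
#' @param lip_radiation spectral tilt from lip radiation, dB/octave
#'   (default +6).
#' @param nose_radiation additional tilt from nasal radiation, dB/octave.
#' @param speed_of_sound cm/s; 35,400 in warm air.
#' @return an object of class `tract_params`.
#' @export
tract_params <- function(vtl = NULL, mouth = 0.5, lip_radiation = 6,
                         nose_radiation = 0,
                         speed_of_sound = SPEED_OF_SOUND) {
  if (!is.null(vtl)) stopifnot_scalar(vtl, "vtl", lo = 0.1)
  structure(list(
    vtl = vtl,
    mouth = contour_spec(mouth, scale = "linear", parameter = "mouth",
                         range = c(0, 1)),
    lip_radiation = lip_radiation, nose_radiation = nose_radiation,
    speed_of_sound = speed_of_sound),
    class = "tract_params")
}

#' Uniform-tube formant frequencies from vocal-tract length
#'
#' `F_n = (2n - 1) * c / (4 * VTL)`: the odd-quarter-wavelength resonances
#' of a uniform tube closed at the glottis, with constant spacing
#' (dispersion) `d = c / (2 * VTL)`.  This is the neutral schwa series.
#'
#' @param vtl vocal-tract length, cm.
#' @param n number of formants.
#' @param speed_of_sound cm/s.
#' @return numeric vector of formant frequencies, Hz.
#' @examples
#' formant_frequencies_from_vtl(17.7, 3)  # 500 1500 2500
#' @export
formant_frequencies_from_vtl <- function(vtl, n,
                                         speed_of_sound = SPEED_OF_SOUND) {
  stopifnot_scalar(vtl, "vtl", lo = 1e-9)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  (2 * seq_len(n) - 1) * speed_of_sound / (4 * vtl)
}

#' Apparent vocal-tract length from observed formants
#'
#' Least-squares inversion of the uniform-tube model: regression through the
#' origin of the observed `F_i` on the odd-harmonic predictor `(2i - 1)`
#' gives the formant-dispersion estimate, hence `VTL = c / (2 * d)`.  Exact
#' inverse of [formant_frequencies_from_vtl()] on exact tube input.
#'
#' @param observed_formants ascending formant frequencies, Hz.
#' @param speed_of_sound cm/s.
#' @return estimated vocal-tract length, cm.
#' @examples
#' estimate_vtl(c(500, 1500, 2500))  # 17.7
#' @export
estimate_vtl <- function(observed_formants,
                         speed_of_sound = SPEED_OF_SOUND) {
  f <- as.numeric(observed_formants)
  if (!length(f) || any(!is.finite(f)) || any(f <= 0))
    stop("`observed_formants` must be positive frequencies", call. = FALSE)
  x <- 2 * seq_along(f) - 1
  beta <- sum(x * f) / sum(x * x)   # F_i ~ beta * (2i - 1); beta = c/(4 VTL)
  speed_of_sound / (4 * beta)
}

#' Extend a formant series with uniform-tube formants up to Nyquist
#'
#' Appends formants above the highest user-specified one at the positions
#' the uniform-tube model predicts for the given vocal-tract length, up to
#' the Nyquist frequency.  User formants are never altered.  When the
#' synthesis temperature is exactly zero the extension is disabled and the
#' table returned unchanged.
#'
#' @param user a [formant_table()] (possibly empty).
#' @param vtl vocal-tract length, cm; NULL estimates it from the mean user
#'   formant frequencies.
#' @param nyquist Hz.
#' @param temperature synthesis temperature; 0 disables extension.
#' @param speed_of_sound cm/s.
#' @return a `formant_table` with appended tube formants (bandwidths left
#'   NULL, i.e. estimated downstream).
#' @export
extend_formants <- function(user, vtl = NULL, nyquist,
                            temperature = 0.025,
                            speed_of_sound = SPEED_OF_SOUND) {
  user <- formant_table(user)
  if (temperature == 0) return(user)
  mean_freqs <- vapply(user$formants,
                       function(f) mean(f$freq$anchors$value), 0)
  if (is.null(vtl)) {
    if (!length(mean_freqs))
      stop("need either `vtl` or at least one user formant", call. = FALSE)
    vtl <- estimate_vtl(mean_freqs, speed_of_sound)
  }
  d <- speed_of_sound / (2 * vtl)
  top <- if (length(mean_freqs)) max(mean_freqs) else 0
  i <- 1L
  new <- list()
  repeat {
    fi <- (2 * i - 1) * d / 2
    if (fi > nyquist) break
    if (fi > top) new[[paste0("f", length(user$formants) + length(new) + 1L)]] <-
        list(freq = fi)
    i <- i + 1L
  }
  if (length(new))
    user$formants <- c(user$formants,
                       formant_table(new)$formants)
  user
}

#' Formant bandwidth from center frequency
#'
#' Empirical piecewise curve used wherever the user supplies no bandwidth:
#' above 500 Hz a gently widening resonance, `B = 50 * (1 + (f / 2500)^2)`
#' Hz; below 500 Hz a correction that widens bandwidths again toward low
#' frequencies, `B = B(500) * (1 + 2 * ((500 - f) / 500)^2)`.  Continuous,
#' strictly positive, and non-increasing as frequency rises toward 500 Hz.
#'
#' @param frequency formant frequency in Hz (vectorized, > 0).
#' @return bandwidths, Hz.
#' @export
estimate_bandwidth <- function(frequency) {
  if (any(!is.finite(frequency)) || any(frequency <= 0))
    stop("`frequency` must be positive", call. = FALSE)
  b500 <- 50 * (1 + (500 / 2500) ^ 2)
  ifelse(frequency >= 500,
         50 * (1 + (frequency / 2500) ^ 2),
         b500 * (1 + 2 * ((500 - frequency) / 500) ^ 2))
}

## --- realized per-frame formant structure -------------------------------
## freq/width: matrices n_formants x n_frames; amp/strength: vectors.
realize_formants <- function(ft, n_frames) {
  ft <- formant_table(ft)
  real1 <- function(group) {
    k <- length(group)
    freq <- matrix(0, k, n_frames)
    width <- matrix(NA_real_, k, n_frames)
    amp <- numeric(k); strength <- numeric(k)
    for (i in seq_len(k)) {
      f <- group[[i]]
      freq[i, ] <- sample_contour(f$freq, duration = 1,
                                  rate = n_frames)$values
      if (!is.null(f$width)) width[i, ] <- f$width
      amp[i] <- f$amp; strength[i] <- f$strength
    }
    list(freq = freq, width = width, amp = amp, strength = strength)
  }
  structure(list(poles = real1(ft$formants),
                 zeros = real1(ft$antiformants),
                 n_frames = n_frames),
            class = "formant_frames")
}

## fill missing bandwidths from the frequency-based estimator
fill_bandwidths <- function(fr) {
  for (g in c("poles", "zeros")) {
    miss <- is.na(fr[[g]]$width) & is.finite(fr[[g]]$freq)
    if (any(miss))
      fr[[g]]$width[miss] <- estimate_bandwidth(fr[[g]]$freq[miss])
  }
  fr
}

#' Shift formants for mouth opening; nasalize when the mouth is closed
#'
#' Every formant frequency is shifted by `dF(t) = (m(t) - 0.5) * c / (4 *
#' VTL)` -- zero at the neutral opening 0.5, negative toward a closed mouth,
#' positive toward a fully open one -- and floored at a small positive
#' minimum.  At frames where the mouth is fully closed (`m = 0`) the sound
#' is nasalized: the first formant's bandwidth is set to 175 Hz and a
#' zero-pole pair is inserted in the vicinity of F1 (zero at F1 - 100 Hz,
#' pole at F1 + 100 Hz, both 100 Hz wide).
#'
#' @param formants a [formant_table()] or realized `formant_frames`.
#' @param mouth a [sample_contour()] result (or numeric vector) of mouth
#'   opening per frame, values in `[0, 1]`.
#' @param vtl vocal-tract length, cm.
#' @param speed_of_sound cm/s.
#' @return a `formant_frames` object with per-frame adjusted frequencies.
#' @export
adjust_for_mouth <- function(formants, mouth, vtl,
                             speed_of_sound = SPEED_OF_SOUND) {
  m <- if (inherits(mouth, "sampled_contour")) mouth$values
       else as.numeric(mouth)
  if (any(m < 0 | m > 1))
    stop("mouth opening must lie in [0, 1]", call. = FALSE)
  fr <- if (inherits(formants, "formant_frames")) formants
        else realize_formants(formants, n_frames = length(m))
  if (length(m) != fr$n_frames)
    stop("mouth contour length does not match the frame count",
         call. = FALSE)
  fr <- fill_bandwidths(fr)
  dF <- (m - 0.5) * speed_of_sound / (4 * vtl)
  shift <- function(mat) {
    if (!nrow(mat)) return(mat)
    pmax(sweep(mat, 2, dF, `+`), 10)
  }
  fr$poles$freq <- shift(fr$poles$freq)
  fr$zeros$freq <- shift(fr$zeros$freq)
  closed <- which(m == 0)
  if (length(closed) && nrow(fr$poles$freq)) {
    f1 <- fr$poles$freq[1L, ]
    fr$poles$width[1L, closed] <- 175
    nz <- matrix(NA_real_, 1L, fr$n_frames)  # NA = inactive at that frame
    np <- nzw <- npw <- nz
    nz[1L, closed] <- pmax(f1[closed] - 100, 10)
    np[1L, closed] <- f1[closed] + 100
    nzw[1L, closed] <- 100; npw[1L, closed] <- 100
    fr$zeros$freq <- rbind(fr$zeros$freq, nz)
    fr$zeros$width <- rbind(fr$zeros$width, nzw)
    fr$zeros$amp <- c(fr$zeros$amp, 0)
    fr$zeros$strength <- c(fr$zeros$strength, 1)
    fr$poles$freq <- rbind(fr$poles$freq, np)
    fr$poles$width <- rbind(fr$poles$width, npw)
    fr$poles$amp <- c(fr$poles$amp, 0)
    fr$poles$strength <- c(fr$poles$strength, 1)
  }
  fr
}

## STFT geometry descriptor for envelope computation
stft_geometry <- function(sampling_rate, n_frames, n_fft = STFT_N,
                          hop = STFT_HOP) {
  list(sampling_rate = sampling_rate, n_frames = n_frames, n_fft = n_fft,
       hop = hop, freqs = stft_bin_freqs(sampling_rate, n_fft))
}

## magnitude response of one conjugate pole pair (gain 1 at DC, peak ~F):
## |T(f)| with sigma = pi*B, omega_0 = 2*pi*F
resonance_gain <- function(f, F0, B) {
  s2 <- (pi * B) ^ 2
  w <- 2 * pi * f
  w0 <- 2 * pi * F0
  (s2 + w0 ^ 2) / sqrt((s2 + (w - w0) ^ 2) * (s2 + (w + w0) ^ 2))
}

#' Vocal-tract transfer function on the STFT grid
#'
#' Per frame, the gain at each frequency bin is the product of second-order
#' resonance magnitude responses over the poles (formants), divided by the
#' corresponding terms for zeros (antiformants).  Each pole term is raised
#' to its per-formant `strength` exponent, and a per-formant `amp` (dB)
#' raises or lowers the response around the peak.  Lip and nose radiation
#' add a spectral tilt of `lip_radiation + nose_radiation` dB/octave
#' (referenced to 500 Hz).  An empty table with zero radiation yields the
#' unity envelope.
#'
#' @param formants a [formant_table()] or realized `formant_frames`.
#' @param geometry an STFT geometry; the convenient way to get one is to
#'   pass `sampling_rate` and `n_frames` instead.
#' @param tract a [tract_params()] object (radiation slopes); NULL = no tilt.
#' @param sampling_rate,n_frames shortcut used when `geometry` is NULL.
#' @return an object of class `spectral_envelope`: linear gain matrix `bins
#'   x frames` plus the bin frequencies and geometry.
#' @export
compute_spectral_envelope <- function(formants, geometry = NULL,
                                      tract = NULL,
                                      sampling_rate = NULL, n_frames = NULL) {
  if (is.null(geometry)) {
    if (is.null(sampling_rate) || is.null(n_frames))
      stop("supply `geometry` or both `sampling_rate` and `n_frames`",
           call. = FALSE)
    geometry <- stft_geometry(sampling_rate, n_frames)
  }
  fr <- if (inherits(formants, "formant_frames")) formants
        else realize_formants(formants, geometry$n_frames)
  if (fr$n_frames != geometry$n_frames)
    stop("formant frames do not match the STFT geometry", call. = FALSE)
  fr <- fill_bandwidths(fr)
  if (any(fr$poles$width <= 0, na.rm = TRUE) ||
      any(fr$zeros$width <= 0, na.rm = TRUE))
    stop("formant bandwidths must be > 0", call. = FALSE)
  f <- geometry$freqs
  nb <- length(f)
  gain <- matrix(1, nb, geometry$n_frames)
  apply_group <- function(gain, grp, invert = FALSE) {
    for (i in seq_len(nrow(grp$freq))) {
      for (k in seq_len(ncol(grp$freq))) {
        F0 <- grp$freq[i, k]
        if (is.na(F0)) next  # inactive at this frame
        term <- resonance_gain(f, F0, grp$width[i, k])
        if (grp$strength[i] != 1) term <- term ^ grp$strength[i]
        if (grp$amp[i] != 0)
          term <- term * db_to_lin(grp$amp[i] * term / max(term))
        gain[, k] <- if (invert) gain[, k] / term else gain[, k] * term
      }
    }
    gain
  }
  gain <- apply_group(gain, fr$poles, invert = FALSE)
  gain <- apply_group(gain, fr$zeros, invert = TRUE)
  tilt <- (if (is.null(tract)) 0
           else tract$lip_radiation + tract$nose_radiation)
  if (tilt != 0) {
    fref <- pmax(f, f[2L])  # avoid log(0) at the DC bin
    gain <- gain * db_to_lin(tilt * log2(fref / 500))
  }
  if (!all(is.finite(gain)))
    stop("non-finite gain in the spectral envelope", call. = FALSE)
  structure(list(gain = gain, freqs = f,
                 sampling_rate = geometry$sampling_rate,
                 n_fft = geometry$n_fft, hop = geometry$hop),
            class = "spectral_envelope")
}

#' @export
print.spectral_envelope <- function(x, ...) {
  cat(sprintf("<spectral_envelope: %d bins x %d frames @ %g Hz>\n",
              nrow(x$gain), ncol(x$gain), x$sampling_rate))
  invisible(x)
}

#' Apply a spectral envelope to a waveform
#'
#' STFT the sound, multiply each frame's spectrum by the envelope's gain
#' column, inverse-STFT.  The envelope must share the STFT bin grid; if its
#' frame count differs from the signal's, columns are mapped by relative
#' position.  A unity envelope reproduces the input to floating-point
#' precision, and the operation is linear in the input.
#'
#' @param sound a [waveform()].
#' @param envelope a [spectral_envelope()].
#' @return filtered [waveform()] of the same length.
#' @export
apply_filter <- function(sound, envelope) {
  stopifnot(inherits(sound, "waveform"),
            inherits(envelope, "spectral_envelope"))
  sf <- stft(sound$samples, sound$sampling_rate,
             n_fft = envelope$n_fft, hop = envelope$hop)
  g <- envelope$gain
  if (nrow(g) != nrow(sf$S))
    stop("envelope bin count does not match the STFT geometry",
         call. = FALSE)
  if (ncol(g) != ncol(sf$S)) {
    idx <- pmax(1L, pmin(ncol(g),
                         round(seq(1, ncol(g), length.out = ncol(sf$S)))))
    g <- g[, idx, drop = FALSE]
  }
  sf$S <- sf$S * g
  waveform(istft(sf), sound$sampling_rate)
}
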