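## Acoustic verification: the package measures its own output.  These are
## test oracles for self-synthesized signals (f0 tracking by
## autocorrelation, spectral peak picking, source-rolloff regression,
## spectrograms), not general-purpose audio analysis.

#' Fixed thresholds used by the verification utilities
#'
#' Kept in one place so every measurement in the test-suite is reproducible:
#' `periodicity` -- minimum normalized autocorrelation peak for a frame to
#' count as voiced; `prominence_db` -- minimum prominence of a spectral peak.
#'
#' @export
verify_constants <- list(periodicity = 0.45, prominence_db = 10)

#' Frame-wise fundamental-frequency estimate
#'
#' Autocorrelation-peak pitch tracker: per frame, the normalized
#' autocorrelation is searched for its maximum over the lag range implied by
#' `[floor, ceiling]`, with parabolic interpolation around the peak for
#' sub-sample lag resolution.  Frames whose peak autocorrelation falls below
#' the periodicity threshold are flagged unvoiced (NA).
#'
#' @param sound a [waveform()].
#' @param frame analysis frame length, seconds.
#' @param floor,ceiling pitch search range, Hz (`ceiling` below Nyquist).
#' @return object of class `f0_track`: data.frame with columns `time` (s,
#'   frame centers), `f0` (Hz, NA where unvoiced), `strength` (peak
#'   autocorrelation).
#' @export
estimate_f0 <- function(sound, frame = 0.05, floor = 60, ceiling = 1000) {
  stopifnot(inherits(sound, "waveform"))
  x <- sound$samples
  sr <- sound$sampling_rate
  if (!length(x)) stop("empty sound", call. = FALSE)
  if (!(floor < ceiling && ceiling < sr / 2))
    stop("need floor < ceiling < sampling_rate / 2", call. = FALSE)
  n <- max(32L, as.integer(round(frame * sr)))
  hop <- max(1L, n %/% 2L)
  lag_min <- max(2L, as.integer(base::floor(sr / ceiling)))
  lag_max <- min(n - 2L, as.integer(base::ceiling(sr / floor)))
  starts <- seq(1L, max(1L, length(x) - n + 1L), by = hop)
  res <- lapply(starts, function(i0) {
    seg <- x[i0:(min(i0 + n - 1L, length(x)))]
    seg <- seg - mean(seg)
    if (length(seg) < lag_max + 2L || sum(seg ^ 2) == 0)
      return(c(NA_real_, 0))
    ## autocorrelation via FFT
    m <- length(seg)
    nf <- 2L ^ ceiling(log2(2L * m))
    sp <- stats::fft(c(seg, rep(0, nf - m)))
    ac <- Re(stats::fft(sp * Conj(sp), inverse = TRUE))[1:(lag_max + 2L)]
    ## unbiased estimate: undo the linear taper of the finite window
    ac <- ac / (m - (0:(lag_max + 1L)))
    ac <- ac / ac[1L]
    rng <- lag_min:lag_max
    seg_ac <- ac[rng + 1L]
    best <- max(seg_ac)
    ## prefer the shortest near-maximal period: the unbiased estimate makes
    ## peaks at integer multiples of the true period equally strong
    loc <- which(diff(sign(diff(c(-Inf, seg_ac, -Inf)))) == -2)
    cand <- loc[seg_ac[loc] >= best - 0.02 * abs(best)]
    pk <- rng[if (length(cand)) min(cand) else which.max(seg_ac)]
    pk <- min(pk, lag_max)
    ## parabolic interpolation around the peak lag
    y1 <- ac[pk]; y2 <- ac[pk + 1L]; y3 <- ac[pk + 2L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
    delta <- clamp(delta, -1, 1)
    c(sr / (pk + delta), y2)
  })
  res <- do.call(rbind, res)
  f0 <- res[, 1L]
  strength <- res[, 2L]
  f0[!is.na(f0) & (strength < verify_constants$periodicity |
                     f0 < floor | f0 > ceiling)] <- NA
  structure(data.frame(time = (starts - 1L + n / 2) / sr, f0 = f0,
                       strength = strength),
            class = c("f0_track", "data.frame"))
}

## Welch-averaged power spectrum, one-sided, in dB
welch_spectrum <- function(x, sr, n_fft = 4096L) {
  n_fft <- min(n_fft, 2L ^ base::floor(log2(max(length(x), 64L))))
  if (length(x) < n_fft) x <- c(x, numeric(n_fft - length(x)))
  hop <- n_fft %/% 2L
  w <- hann_window(n_fft)
  starts <- seq(1L, max(1L, length(x) - n_fft + 1L), by = hop)
  nb <- n_fft %/% 2L + 1L
  acc <- numeric(nb)
  for (i0 in starts) {
    seg <- x[i0:(i0 + n_fft - 1L)]
    sp <- stats::fft(seg * w)[1:nb]
    acc <- acc + Mod(sp) ^ 2
  }
  list(freq = (0:(nb - 1L)) * sr / n_fft,
       power_db = 10 * log10(pmax(acc / length(starts),
                                  .Machine$double.xmin)),
       n_frames = length(starts), bin_width = sr / n_fft)
}

## peak prominence by walking to the nearest higher point on each side
find_peaks <- function(y, prominence) {
  n <- length(y)
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  keep <- vapply(is_max, function(i) {
    j <- i; lo_l <- y[i]
    while (j > 1L && y[j - 1L] <= y[i]) { j <- j - 1L; lo_l <- min(lo_l, y[j]) }
    k <- i; lo_r <- y[i]
    while (k < n && y[k + 1L] <= y[i]) { k <- k + 1L; lo_r <- min(lo_r, y[k]) }
    (y[i] - max(lo_l, lo_r)) >= prominence
  }, TRUE)
  is_max[keep]
}

#' Spectral peaks and source-rolloff measurement
#'
#' Peaks are local maxima of the Welch-averaged power spectrum with at least
#' `prominence_db` of prominence.  When `f0_hint` is given, the level of
#' each harmonic (maximum within +/- 2 bins of `h * f0_hint`) is regressed
#' on `log2(h)`, giving the fitted source rolloff slope in dB/octave.
#'
#' @param sound a [waveform()].
#' @param f0_hint fundamental frequency in Hz, or NULL to skip rolloff
#'   fitting.
#' @param n_fft Welch segment length (power of two).
#' @param max_harmonics cap on the number of harmonics entering the fit.
#' @param prominence_db peak prominence threshold (defaults to the package
#'   constant).
#' @return object of class `spectral_measurement`: list with `peaks`
#'   (data.frame `freq`, `level_db`), `rolloff_slope` (dB/octave or NA),
#'   `harmonics` (levels used in the fit), `bin_width`, `n_frames`.
#' @export
measure_peaks_and_rolloff <- function(sound, f0_hint = NULL, n_fft = 4096L,
                                      max_harmonics = 20L,
                                      prominence_db =
                                        verify_constants$prominence_db) {
  stopifnot(inherits(sound, "waveform"))
  x <- sound$samples
  sr <- sound$sampling_rate
  if (!length(x) || max(abs(x)) == 0) {
    return(structure(list(peaks = data.frame(freq = numeric(0),
                                             level_db = numeric(0)),
                          rolloff_slope = NA_real_,
                          harmonics = NULL, bin_width = NA_real_,
                          n_frames = 0L),
                     class = "spectral_measurement"))
  }
  ws <- welch_spectrum(x, sr, n_fft)
  idx <- find_peaks(ws$power_db, prominence_db)
  ## drop peaks buried far below the spectrum maximum (noise-floor ripple)
  idx <- idx[ws$power_db[idx] > max(ws$power_db) - 80]
  peaks <- data.frame(freq = ws$freq[idx], level_db = ws$power_db[idx])
  slope <- NA_real_
  harm <- NULL
  if (!is.null(f0_hint) && f0_hint > 0) {
    h_max <- min(max_harmonics, base::floor((sr / 2 - ws$bin_width) / f0_hint))
    if (h_max >= 2) {
      lev <- vapply(seq_len(h_max), function(h) {
        b <- 1L + round(h * f0_hint / ws$bin_width)
        rng <- max(1L, b - 2L):min(length(ws$power_db), b + 2L)
        max(ws$power_db[rng])
      }, 0)
      harm <- data.frame(h = seq_len(h_max), level_db = lev)
      fit <- stats::lm(level_db ~ log2(h), data = harm)
      slope <- unname(stats::coef(fit)[2L])
    }
  }
  structure(list(peaks = peaks, rolloff_slope = slope, harmonics = harm,
                 bin_width = ws$bin_width, n_frames = ws$n_frames),
            class = "spectral_measurement")
}

#' @export
print.spectral_measurement <- function(x, ...) {
  cat(sprintf("<spectral_measurement: %d peak(s), rolloff %s dB/oct>\n",
              nrow(x$peaks),
              if (is.na(x$rolloff_slope)) "NA"
              else sprintf("%.1f", x$rolloff_slope)))
  invisible(x)
}

#' Spectrogram display
#'
#' Renders the STFT magnitude (dB) of a waveform with [graphics::image()];
#' set `file` to write a PNG instead of drawing on the current device.
#'
#' @param sound a [waveform()].
#' @param dynamic_range dB below the maximum to display.
#' @param file optional PNG path.
#' @param main plot title.
#' @param ... ignored.
#' @return invisibly, the dB matrix (bins x frames).
#' @export
spectrogram <- function(sound, dynamic_range = 60, file = NULL,
                        main = "", ...) {
  stopifnot(inherits(sound, "waveform"))
  sf <- stft(sound$samples, sound$sampling_rate)
  db <- 20 * log10(pmax(Mod(sf$S), .Machine$double.xmin))
  db <- pmax(db, max(db) - dynamic_range)
  tt <- (seq_len(ncol(db)) - 1L) * sf$hop / sound$sampling_rate
  ff <- stft_bin_freqs(sound$sampling_rate) / 1000
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::image(tt, ff, t(db), col = grDevices::hcl.colors(128, "Grays",
                                                             rev = TRUE),
                  xlab = "time, s", ylab = "frequency, kHz", main = main,
                  useRaster = TRUE)
  invisible(db)
}
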