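## Shared STFT geometry: one analysis/resynthesis pipeline (1024-sample Hann
## frames, 75% overlap) is used for noise synthesis, vocal-tract filtering
## and spectral measurement, so there is a single reconstruction tolerance.

STFT_N   <- 1024L  # frame length, samples
STFT_HOP <- 256L   # hop, samples (75% overlap)

## periodic Hann window: sum of squared shifted copies at hop N/4 is the
## constant 3/2, giving exact weighted overlap-add reconstruction
hann_window <- function(n = STFT_N) {
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / n)
}

## Forward STFT.  The signal is zero-padded by one frame on each side so
## every sample receives full window coverage; the padding is removed by
## istft().  Returns the one-sided complex spectrogram (n/2 + 1 bins).
stft <- function(x, sampling_rate, n_fft = STFT_N, hop = STFT_HOP) {
  stopifnot(is.numeric(x), sampling_rate > 0)
  w <- hann_window(n_fft)
  pad <- n_fft
  nx <- length(x)
  n_frames <- max(1L, as.integer(ceiling((nx + pad) / hop)))
  total <- (n_frames - 1L) * hop + n_fft
  xp <- c(rep(0, pad), x, rep(0, total - nx - pad))
  nb <- n_fft %/% 2L + 1L
  S <- matrix(0i, nrow = nb, ncol = n_frames)
  for (k in seq_len(n_frames)) {
    i0 <- (k - 1L) * hop
    fr <- stats::fft(xp[(i0 + 1L):(i0 + n_fft)] * w)
    S[, k] <- fr[1:nb]
  }
  structure(list(S = S, sampling_rate = sampling_rate, n_fft = n_fft,
                 hop = hop, pad = pad, n_samples = nx),
            class = "stft_frames")
}

## Inverse STFT by weighted overlap-add (synthesis window = analysis window,
## normalized by the constant 3/2 window-square sum).  Inverts stft() to
## floating-point precision.
istft <- function(sf, n_samples = sf$n_samples) {
  S <- sf$S
  n_fft <- sf$n_fft
  hop <- sf$hop
  w <- hann_window(n_fft)
  nb <- nrow(S)
  n_frames <- ncol(S)
  total <- (n_frames - 1L) * hop + n_fft
  out <- numeric(total)
  for (k in seq_len(n_frames)) {
    full <- c(S[, k], Conj(rev(S[2:(nb - 1L), k])))
    frame <- Re(stats::fft(full, inverse = TRUE)) / n_fft
    i0 <- (k - 1L) * hop
    out[(i0 + 1L):(i0 + n_fft)] <- out[(i0 + 1L):(i0 + n_fft)] + frame * w
  }
  out <- out / 1.5
  out[(sf$pad + 1L):(sf$pad + n_samples)]
}

## number of STFT frames stft() will produce for nx samples
stft_n_frames <- function(nx, n_fft = STFT_N, hop = STFT_HOP) {
  max(1L, as.integer(ceiling((nx + n_fft) / hop)))
}

## center frequencies (Hz) of the one-sided bins
stft_bin_freqs <- function(sampling_rate, n_fft = STFT_N) {
  (0:(n_fft %/% 2L)) * sampling_rate / n_fft
}
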