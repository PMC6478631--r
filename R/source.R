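## Voiced excitation: a stack of sine-wave harmonics.  Each harmonic h is a
## sine with instantaneous frequency h * f0(t) and zero initial phase,
## realized as w_h(t) = a_h(t) * sin(2*pi*h/s * cumsum(f0)); the source
## waveform is the sum over h, with no component ever synthesized above the
## Nyquist frequency.  Nonlinear phenomena ride on top: jitter and shimmer
## perturb frequency and amplitude, subharmonics insert components at
## multiples of g0 = f0 / sub_ratio, and "chaos" is strong jitter + shimmer,
## gated by a thresholded random walk over time.

#' Voiced-source parameter set
#'
#' Bundles every control of the glottal (voiced) excitation.  All depths
#' default to zero, i.e. a plain tonal source.
#'
#' @param f0 fundamental-frequency contour: anchors in Hz (see
#'   [contour_spec()]); interpolated on the log scale.
#' @param ampl amplitude envelope of the voiced component, anchors in dB
#'   relative to full scale (0 = unity).
#' @param rolloff source spectral slope, dB per octave: each octave above f0
#'   the harmonic power drops by `rolloff` dB (>= 0).
#' @param rolloff_shape optional function `(h, f0) -> dB` of additional
#'   per-harmonic gain, a hook for non-exponential source spectra.
#' @param vibrato_freq,vibrato_depth sinusoidal f0 modulation: rate in Hz and
#'   depth in semitones.
#' @param jitter_depth,jitter_period stochastic f0 fluctuation: SD in
#'   semitones and correlation length in seconds.
#' @param shimmer_depth cycle-to-cycle amplitude fluctuation, SD as a
#'   fraction of the amplitude.
#' @param attack_len fade-in/out applied at segment edges, seconds.
#' @param am_depth,am_freq,am_shape low-frequency amplitude modulation:
#'   depth as a fraction in `[0, 1]`, rate in Hz, and a waveform-shape
#'   exponent (1 = sinusoidal; larger values sharpen the troughs into
#'   trill-like pulses).
#' @param sub_ratio integer ratio f0/g0 (>= 1); 1 disables subharmonics.
#' @param sub_depth level of subharmonic components, dB below the local
#'   harmonic envelope (larger = weaker; `Inf` silences them).
#' @param chaos_jitter,chaos_shimmer jitter (semitones) and shimmer
#'   (fraction) applied in frames labelled as chaotic by the regime track.
#' @return an object of class `source_params`.
#' @export
source_params <- function(f0 = 120, ampl = 0, rolloff = 12,
                          rolloff_shape = NULL,
                          vibrato_freq = 5, vibrato_depth = 0,
                          jitter_depth = 0, jitter_period = 0.02,
                          shimmer_depth = 0,
                          attack_len = 0.01,
                          am_depth = 0, am_freq = 30, am_shape = 1,
                          sub_ratio = 1L, sub_depth = 12,
                          chaos_jitter = 1.5, chaos_shimmer = 0.25) {
  stopifnot_scalar(rolloff, "rolloff", lo = 0)
  stopifnot_scalar(vibrato_depth, "vibrato_depth", lo = 0)
  stopifnot_scalar(jitter_depth, "jitter_depth", lo = 0)
  stopifnot_scalar(jitter_period, "jitter_period", lo = 1e-4)
  stopifnot_scalar(shimmer_depth, "shimmer_depth", lo = 0, hi = 1)
  stopifnot_scalar(am_depth, "am_depth", lo = 0, hi = 1)
  stopifnot_scalar(attack_len, "attack_len", lo = 0)
  if (length(sub_ratio) != 1L || sub_ratio < 1 ||
      abs(sub_ratio - round(sub_ratio)) > 1e-9)
    stop("`sub_ratio` must be a single integer >= 1", call. = FALSE)
  if (!(is.numeric(sub_depth) && length(sub_depth) == 1L &&
        (is.finite(sub_depth) || sub_depth == Inf)))
    stop("`sub_depth` must be a single number (Inf allowed)", call. = FALSE)
  structure(list(
    f0 = contour_spec(f0, scale = "log", parameter = "f0",
                      range = c(0.01, 1e5)),
    ampl = contour_spec(ampl, scale = "linear", parameter = "ampl"),
    rolloff = rolloff, rolloff_shape = rolloff_shape,
    vibrato_freq = vibrato_freq, vibrato_depth = vibrato_depth,
    jitter_depth = jitter_depth, jitter_period = jitter_period,
    shimmer_depth = shimmer_depth, attack_len = attack_len,
    am_depth = am_depth, am_freq = am_freq, am_shape = am_shape,
    sub_ratio = as.integer(round(sub_ratio)), sub_depth = sub_depth,
    chaos_jitter = chaos_jitter, chaos_shimmer = chaos_shimmer,
    jitter_track = NULL, shimmer_track = NULL),
    class = "source_params")
}

#' Nonlinear-regime track from a bounded random walk
#'
#' A seeded Gaussian random walk, reflected into `[0, 1]` and smoothed by a
#' moving average, is shifted by the `nonlinear_balance` hyperparameter and
#' thresholded into three regimes: below `thresholds[1]` no nonlinear
#' effects, between the thresholds subharmonics, above `thresholds[2]`
#' subharmonics plus chaos.  `nonlinear_balance = 0` forces the walk below
#' the first threshold (an entirely tonal sound); `1` forces it above the
#' second (chaos throughout).
#'
#' @param duration voiced-segment duration, seconds.
#' @param nonlinear_balance fraction in `[0, 1]`.
#' @param thresholds increasing pair of walk levels in `(0, 1)`.
#' @param walk_smoothness moving-average width, frames.
#' @param frame_rate label rate, frames per second.
#' @param seed integer seed, or NULL.
#' @return object of class `regime_track`: list with `labels` (factor with
#'   levels none / subharmonics / subharmonics+chaos), `frame_rate`,
#'   `duration`, and the underlying `walk`.
#' @export
generate_regime_track <- function(duration, nonlinear_balance = 0,
                                  thresholds = c(0.5, 0.8),
                                  walk_smoothness = 10,
                                  frame_rate = 100, seed = NULL) {
  stopifnot_scalar(duration, "duration", lo = 1e-9)
  stopifnot_scalar(nonlinear_balance, "nonlinear_balance", lo = 0, hi = 1)
  if (length(thresholds) != 2L || !all(is.finite(thresholds)) ||
      thresholds[1L] >= thresholds[2L] ||
      thresholds[1L] <= 0 || thresholds[2L] >= 1)
    stop("`thresholds` must be an increasing pair inside (0, 1)",
         call. = FALSE)
  n <- max(1L, as.integer(round(duration * frame_rate)))
  walk <- with_seed(seed, {
    w <- cumsum(stats::rnorm(n, 0, 0.05))
    ## reflect into [0, 1]
    w <- abs((w + 0.5) %% 2 - 1)
    smooth_ma(w, walk_smoothness)
  })
  walk <- clamp(walk + 2 * (nonlinear_balance - 0.5), 0, 1)
  lv <- c("none", "subharmonics", "subharmonics+chaos")
  lab <- lv[1L + (walk >= thresholds[1L]) + (walk >= thresholds[2L])]
  structure(list(labels = factor(lab, levels = lv), frame_rate = frame_rate,
                 duration = duration, walk = walk),
            class = "regime_track")
}

#' @export
print.regime_track <- function(x, ...) {
  cat(sprintf("<regime_track: %d frames @ %g/s>\n", length(x$labels),
              x$frame_rate))
  print(table(x$labels))
  invisible(x)
}

## upsample per-frame regime labels to a per-sample logical mask
regime_mask <- function(regimes, n_samples, sampling_rate,
                        which = c("subharmonics", "subharmonics+chaos")) {
  if (is.null(regimes)) return(rep(TRUE, n_samples))
  idx <- pmin(length(regimes$labels),
              1L + floor((seq_len(n_samples) - 1L) / sampling_rate *
                           regimes$frame_rate))
  as.character(regimes$labels)[idx] %in% which
}

## upsample a per-frame numeric track to per-sample values
frame_to_samples <- function(track, frame_rate, n_samples, sampling_rate) {
  idx <- pmin(length(track),
              1L + floor((seq_len(n_samples) - 1L) / sampling_rate *
                           frame_rate))
  track[idx]
}

#' Raise jitter and shimmer to chaotic levels in chaos frames
#'
#' Deterministic chaos is simulated as strong jitter plus strong shimmer.
#' This replaces the scalar depths with per-frame depth tracks: baseline
#' `jitter_depth` / `shimmer_depth` everywhere, raised to `chaos_jitter` /
#' `chaos_shimmer` in frames the regime track labels `subharmonics+chaos`.
#'
#' @param params a [source_params()] object.
#' @param regimes a [generate_regime_track()] result (NULL = no change).
#' @return `params` with `jitter_track` and `shimmer_track` fields set
#'   (numeric per-frame depths plus a `frame_rate` attribute).
#' @export
apply_chaos <- function(params, regimes) {
  stopifnot(inherits(params, "source_params"))
  if (is.null(regimes)) return(params)
  chaos <- as.character(regimes$labels) == "subharmonics+chaos"
  jt <- ifelse(chaos, pmax(params$chaos_jitter, params$jitter_depth),
               params$jitter_depth)
  st <- ifelse(chaos, pmax(params$chaos_shimmer, params$shimmer_depth),
               params$shimmer_depth)
  attr(jt, "frame_rate") <- regimes$frame_rate
  attr(st, "frame_rate") <- regimes$frame_rate
  params$jitter_track <- jt
  params$shimmer_track <- st
  params
}

## smooth unit-SD noise with the requested correlation length; empirically
## renormalized so the realized SD is exactly 1
smooth_noise <- function(n, corr_len_samples) {
  z <- stats::rnorm(n)
  z <- smooth_ma(z, corr_len_samples)
  s <- stats::sd(z)
  if (!is.finite(s) || s == 0) return(numeric(n))
  (z - mean(z)) / s
}

#' Per-sample fundamental-frequency track
#'
#' Densifies the f0 anchor contour and applies vibrato (a deterministic
#' sinusoidal factor `2^(depth * sin(2*pi*freq*t) / 12)`) and jitter (a
#' seeded smooth random fluctuation on the semitone scale with SD equal to
#' the jitter depth and correlation length `jitter_period`).  When the
#' parameters carry a per-frame jitter track (see [apply_chaos()]), the
#' jitter depth varies over time accordingly.
#'
#' @param params a [source_params()] object.
#' @param duration seconds.
#' @param sampling_rate Hz.
#' @param regimes optional [generate_regime_track()] result; only used via
#'   the depth tracks installed by [apply_chaos()].
#' @param seed integer seed for the jitter draw, or NULL.
#' @return numeric vector of per-sample f0 values (Hz).
#' @export
compute_f0_track <- function(params, duration, sampling_rate,
                             regimes = NULL, seed = NULL) {
  stopifnot(inherits(params, "source_params"))
  base <- sample_contour(params$f0, duration, sampling_rate)$values
  n <- length(base)
  t <- (seq_len(n) - 1L) / sampling_rate
  semitones <- numeric(n)
  if (params$vibrato_depth > 0)
    semitones <- semitones +
      params$vibrato_depth * sin(2 * pi * params$vibrato_freq * t)
  depth <- if (!is.null(params$jitter_track))
    frame_to_samples(params$jitter_track, attr(params$jitter_track,
                                               "frame_rate"),
                     n, sampling_rate)
  else rep(params$jitter_depth, n)
  if (any(depth > 0)) {
    dev <- with_seed(seed,
                     smooth_noise(n, params$jitter_period * sampling_rate))
    semitones <- semitones + dev * depth
  }
  base * 2 ^ (semitones / 12)
}

#' Relative amplitude of harmonic h under the source rolloff law
#'
#' `10^(-rolloff * log2(h) / 20)`: the fundamental has amplitude 1 and each
#' octave above it loses `rolloff` dB of power.  An optional `rolloff_shape`
#' hook in the parameters adds per-harmonic dB adjustments for
#' non-exponential source spectra.
#'
#' @param h harmonic index (integer >= 1, vectorized).
#' @param f0 fundamental frequency in Hz (passed to the shape hook).
#' @param params a [source_params()] object.
#' @return linear amplitudes in `[0, 1]`.
#' @export
harmonic_amplitudes <- function(h, f0, params) {
  if (any(h < 1)) stop("harmonic index must be >= 1", call. = FALSE)
  db <- -params$rolloff * log2(h)
  if (is.function(params$rolloff_shape))
    db <- db + params$rolloff_shape(h, f0)
  clamp(db_to_lin(db), 0, 1)
}

#' Number of harmonics that fit below the Nyquist frequency
#'
#' @param f0 fundamental frequency, Hz (the maximum of a contour for
#'   time-varying pitch).
#' @param sampling_rate Hz.
#' @return integer count of harmonics h with `h * f0 <= sampling_rate / 2`.
#' @export
harmonic_count <- function(f0, sampling_rate) {
  as.integer(floor((sampling_rate / 2) / max(f0) + 1e-9))
}

#' Component plan for the harmonic stack, including subharmonics
#'
#' Builds the list of sinusoidal components to synthesize: the main
#' harmonics at multiples of f0 and, when `sub_ratio > 1`, subharmonics at
#' multiples of `g0 = f0 / sub_ratio` that are not multiples of f0, at
#' `sub_depth` dB below the harmonic envelope interpolated at their
#' frequency.  Subharmonic components are flagged so synthesis can gate them
#' by the regime track.
#'
#' @param params a [source_params()] object.
#' @param f0_track per-sample f0 (Hz).
#' @param sampling_rate Hz.
#' @param regimes optional regime track; if supplied and no frame is
#'   labelled subharmonic/chaotic, no subharmonic components are planned.
#' @return data.frame with columns `mult` (frequency as a multiple of f0),
#'   `amp` (linear amplitude at unit fundamental), `sub` (logical).
#' @export
add_subharmonics <- function(params, f0_track, sampling_rate,
                             regimes = NULL) {
  stopifnot(inherits(params, "source_params"))
  nyq <- sampling_rate / 2
  f0max <- max(f0_track)
  n_h <- harmonic_count(f0max, sampling_rate)
  plan <- data.frame(mult = seq_len(max(n_h, 1L)))
  plan$amp <- harmonic_amplitudes(plan$mult, f0max, params)
  plan$sub <- FALSE
  k <- params$sub_ratio
  want_sub <- k > 1L && is.finite(params$sub_depth) &&
    (is.null(regimes) ||
       any(regimes$labels %in% c("subharmonics", "subharmonics+chaos")))
  if (want_sub) {
    j <- setdiff(seq_len(floor(nyq / (f0max / k) + 1e-9)),
                 k * seq_len(n_h))
    if (length(j)) {
      mult <- j / k
      ## local harmonic envelope, clamped to the fundamental below f0
      env <- db_to_lin(-params$rolloff * log2(pmax(mult, 1)))
      sub <- data.frame(mult = mult,
                        amp = env * db_to_lin(-params$sub_depth),
                        sub = TRUE)
      plan <- rbind(plan, sub)
    }
  }
  plan[order(plan$mult), , drop = FALSE]
}

#' Additive synthesis of the voiced excitation
#'
#' Sums sine components with zero initial phase: component with frequency
#' multiple `m` contributes `a_m(t) * sin(2*pi*m/s * cumsum(f0))`, silenced
#' wherever its instantaneous frequency `m * f0(t)` would exceed the Nyquist
#' frequency.  Shimmer multiplies the amplitude by a seeded per-glottal-cycle
#' factor with SD `shimmer_depth`; the amplitude envelope, low-frequency
#' amplitude modulation and edge attack fades are applied afterwards.
#'
#' @param f0_track per-sample f0 in Hz (strictly positive).
#' @param params a [source_params()] object.
#' @param sampling_rate Hz.
#' @param seed integer seed for shimmer, or NULL.
#' @param regimes optional regime track gating subharmonics and supplying
#'   per-frame shimmer depths (after [apply_chaos()]).
#' @return a [waveform()] (unfiltered source; not normalized).
#' @export
synthesize_voiced <- function(f0_track, params, sampling_rate, seed = NULL,
                              regimes = NULL) {
  if (!is.numeric(f0_track) || !length(f0_track) || any(f0_track <= 0))
    stop("`f0_track` must be strictly positive", call. = FALSE)
  stopifnot_scalar(sampling_rate, "sampling_rate", lo = 1)
  n <- length(f0_track)
  nyq <- sampling_rate / 2
  phase <- 2 * pi * cumsum(f0_track) / sampling_rate
  plan <- add_subharmonics(params, f0_track, sampling_rate, regimes)
  submask <- if (any(plan$sub))
    regime_mask(regimes, n, sampling_rate) else NULL
  out <- numeric(n)
  for (i in seq_len(nrow(plan))) {
    m <- plan$mult[i]
    if (plan$amp[i] <= 0) next
    audible <- m * f0_track <= nyq
    if (!any(audible)) next
    comp <- plan$amp[i] * sin(m * phase)
    comp[!audible] <- 0
    if (plan$sub[i] && !is.null(submask)) comp[!submask] <- 0
    out <- out + comp
  }
  ## shimmer: per-cycle multiplicative amplitude factor
  shim_depth <- if (!is.null(params$shimmer_track))
    frame_to_samples(params$shimmer_track,
                     attr(params$shimmer_track, "frame_rate"),
                     n, sampling_rate)
  else rep(params$shimmer_depth, n)
  if (any(shim_depth > 0)) {
    cycle <- 1L + floor(phase / (2 * pi))
    z <- with_seed(seed, stats::rnorm(max(cycle)))
    fac <- 1 + z[cycle] * shim_depth
    out <- out * clamp(fac, 0.05, 2)
  }
  ## amplitude envelope (dB), AM, attack
  env_db <- sample_contour(params$ampl, n / sampling_rate,
                           sampling_rate)$values
  env_db <- env_db[seq_len(min(n, length(env_db)))]
  if (length(env_db) < n) env_db <- c(env_db, rep(env_db[length(env_db)],
                                                  n - length(env_db)))
  out <- out * db_to_lin(env_db)
  if (params$am_depth > 0) {
    t <- (seq_len(n) - 1L) / sampling_rate
    carrier <- (0.5 + 0.5 * sin(2 * pi * params$am_freq * t)) ^
      params$am_shape
    out <- out * (1 - params$am_depth * carrier)
  }
  out <- apply_attack(out, params$attack_len, sampling_rate)
  waveform(out, sampling_rate)
}

## raised-cosine fade of `len` seconds at both edges
apply_attack <- function(x, len, sampling_rate) {
  na <- min(floor(len * sampling_rate), floor(length(x) / 2))
  if (na < 1L) return(x)
  ramp <- 0.5 - 0.5 * cos(pi * (seq_len(na) - 0.5) / na)
  x[seq_len(na)] <- x[seq_len(na)] * ramp
  x[(length(x) - na + 1L):length(x)] <-
    x[(length(x) - na + 1L):length(x)] * rev(ramp)
  x
}
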