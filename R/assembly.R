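## Top-level synthesis: bout/syllable structure, the hyperparameters
## (temperature, maleFemale), voiced/unvoiced mixing, peak normalization,
## and morphing between complete parameter sets.

PEAK_TARGET <- 0.995  # final peak normalization (~ -0.04 dBFS)

#' Sampled audio container
#'
#' @param samples numeric vector of amplitudes.
#' @param sampling_rate Hz.
#' @return an object of class `waveform`.
#' @export
waveform <- function(samples, sampling_rate) {
  stopifnot(is.numeric(samples))
  stopifnot_scalar(sampling_rate, "sampling_rate", lo = 1)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("<waveform: %.3f s (%d samples) @ %g Hz, peak %.3f>\n",
              n / x$sampling_rate, n, x$sampling_rate,
              if (n) max(abs(x$samples)) else 0))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' @rdname spectrogram
#' @param x a `waveform` (plot method).
#' @param ... passed on to [spectrogram()].
#' @export
plot.waveform <- function(x, ...) spectrogram(x, ...)

## scale so that max |sample| hits the peak target
normalize_peak <- function(x, target = PEAK_TARGET) {
  if (!length(x$samples)) return(x)
  pk <- max(abs(x$samples))
  if (pk > 0) x$samples <- x$samples * (target / pk)
  x
}

#' Complete control-parameter set for one vocalization
#'
#' Bundles everything [synthesize()] needs: bout structure, voiced and noise
#' sources, formants, vocal-tract geometry, and the hyperparameters.
#'
#' @param n_syllables number of syllables per bout.
#' @param syllable_len syllable length(s) in ms: a single value or anchors
#'   across the syllable index.
#' @param pause_len pause length(s) between syllables, ms.
#' @param repeat_bout number of times the whole bout is repeated.
#' @param source a [source_params()] object.
#' @param noise a [noise_params()] object.
#' @param formants a [formant_table()] (possibly empty: with `vtl` set, a
#'   neutral schwa series is generated; with neither, no filtering).
#' @param tract a [tract_params()] object.
#' @param voiced logical: synthesize the harmonic component?  `FALSE` gives
#'   a purely voiceless (noise-only) sound.
#' @param nonlinear_balance,regime_thresholds,walk_smoothness,regime_frame_rate
#'   controls of the nonlinear-regime random walk, see
#'   [generate_regime_track()].
#' @param temperature non-negative; scales all stochastic variation.  Zero
#'   disables both the variation and the addition of tube-model formants
#'   above the user-specified ones (a small positive value is the
#'   recommended way to get precise but fully specified output).
#' @param male_female in `[-1, 1]`: 0 = neutral, +1 shifts f0 an octave
#'   down and lengthens the vocal tract by 25%, -1 the reverse.
#' @param sampling_rate output rate, Hz (22050 by convention).
#' @param seed default seed used by [synthesize()]; NULL = nondeterministic.
#' @return an object of class `synth_config`.
#' @examples
#' cfg <- synth_config(source = source_params(f0 = c(150, 130)),
#'                     tract = tract_params(vtl = 17.7))
#' @export
synth_config <- function(n_syllables = 1L, syllable_len = 300,
                         pause_len = 100, repeat_bout = 1L,
                         source = source_params(),
                         noise = noise_params(),
                         formants = formant_table(),
                         tract = tract_params(),
                         voiced = TRUE,
                         nonlinear_balance = 0,
                         regime_thresholds = c(0.5, 0.8),
                         walk_smoothness = 10,
                         regime_frame_rate = 100,
                         temperature = 0.025,
                         male_female = 0,
                         sampling_rate = 22050,
                         seed = NULL) {
  if (n_syllables < 1) stop("`n_syllables` must be >= 1", call. = FALSE)
  if (repeat_bout < 1) stop("`repeat_bout` must be >= 1", call. = FALSE)
  stopifnot_scalar(temperature, "temperature", lo = 0)
  stopifnot_scalar(male_female, "male_female", lo = -1, hi = 1)
  stopifnot_scalar(sampling_rate, "sampling_rate", lo = 1)
  structure(list(
    bout = list(
      n_syllables = as.integer(n_syllables),
      syllable_len = contour_spec(syllable_len, parameter = "syl_len",
                                  range = c(1, 60000)),
      pause_len = contour_spec(pause_len, parameter = "pause_len",
                               range = c(0, 60000)),
      repeat_bout = as.integer(repeat_bout)),
    source = source, noise = noise,
    formants = formant_table(formants),
    tract = tract,
    voiced = isTRUE(voiced),
    nonlinear_balance = nonlinear_balance,
    regime_thresholds = regime_thresholds,
    walk_smoothness = walk_smoothness,
    regime_frame_rate = regime_frame_rate,
    temperature = temperature, male_female = male_female,
    sampling_rate = sampling_rate, seed = seed),
    class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  f0a <- x$source$f0$anchors
  cat(sprintf(paste0("<synth_config: %d syllable(s) x %s ms, f0 [%g, %g] Hz,",
                     " %d formant(s), temperature %g, %g Hz>\n"),
              x$bout$n_syllables,
              paste(round(x$bout$syllable_len$anchors$value),
                    collapse = "/"),
              min(f0a$value), max(f0a$value),
              length(x$formants$formants), x$temperature, x$sampling_rate))
  invisible(x)
}

#' Coordinated f0 / vocal-tract shift along the male-female axis
#'
#' `male_female = 0` returns the configuration unchanged.  A value of +1
#' halves every f0 anchor (one octave down) and lengthens the vocal tract by
#' a factor 1.25 (scaling user formant frequencies down accordingly, so that
#' tube-extended formants stay consistent); -1 applies the inverse.
#' Intermediate values interpolate smoothly: f0 is scaled by `2^(-mf)` and
#' VTL by `1.25^mf`.  The returned configuration has `male_female` reset to
#' 0, so the mapping is applied exactly once.
#'
#' @param config a [synth_config()].
#' @return the adjusted `synth_config`.
#' @export
apply_male_female <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  mf <- config$male_female
  if (mf < -1 || mf > 1)
    stop("`male_female` must lie in [-1, 1]", call. = FALSE)
  if (mf == 0) return(config)
  config$source$f0$anchors$value <- config$source$f0$anchors$value * 2 ^ (-mf)
  vtl_fac <- 1.25 ^ mf
  if (!is.null(config$tract$vtl)) config$tract$vtl <- config$tract$vtl * vtl_fac
  for (i in seq_along(config$formants$formants))
    config$formants$formants[[i]]$freq$anchors$value <-
      config$formants$formants[[i]]$freq$anchors$value / vtl_fac
  for (i in seq_along(config$formants$antiformants))
    config$formants$antiformants[[i]]$freq$anchors$value <-
      config$formants$antiformants[[i]]$freq$anchors$value / vtl_fac
  config$male_female <- 0
  config
}

## effective vocal-tract length for a config: explicit, or estimated from
## the user formants; NULL if neither is available (=> no filtering)
effective_vtl <- function(config) {
  if (!is.null(config$tract$vtl)) return(config$tract$vtl)
  fr <- vapply(config$formants$formants,
               function(f) mean(f$freq$anchors$value), 0)
  if (length(fr)) estimate_vtl(fr, config$tract$speed_of_sound) else NULL
}

## synthesize one syllable (voiced + noise, filtered); duration in seconds
synth_syllable <- function(config, duration) {
  sr <- config$sampling_rate
  n <- as.integer(round(duration * sr))
  regimes <- generate_regime_track(
    duration, config$nonlinear_balance, config$regime_thresholds,
    config$walk_smoothness, config$regime_frame_rate)
  src <- apply_chaos(config$source, regimes)
  src$f0 <- wiggle_contour(src$f0, config$temperature)
  vtl <- effective_vtl(config)
  env <- NULL
  if (!is.null(vtl) || length(config$formants$formants)) {
    n_frames <- stft_n_frames(n)
    ft <- extend_formants(config$formants, vtl = vtl, nyquist = sr / 2,
                          temperature = config$temperature,
                          speed_of_sound = config$tract$speed_of_sound)
    mouth <- sample_contour(config$tract$mouth, duration,
                            rate = n_frames / duration)
    mval <- mouth$values[seq_len(min(n_frames, length(mouth$values)))]
    if (length(mval) < n_frames)
      mval <- c(mval, rep(mval[length(mval)], n_frames - length(mval)))
    fr <- adjust_for_mouth(realize_formants(ft, n_frames), mval,
                           vtl %||% estimate_vtl(
                             vapply(ft$formants,
                                    function(f) mean(f$freq$anchors$value),
                                    0)),
                           config$tract$speed_of_sound)
    env <- compute_spectral_envelope(fr, stft_geometry(sr, n_frames),
                                     config$tract)
  }
  voiced <- waveform(numeric(0), sr)
  if (config$voiced) {
    f0_track <- compute_f0_track(src, duration, sr, regimes)
    voiced <- synthesize_voiced(f0_track, src, sr, regimes = regimes)
    if (!is.null(env)) voiced <- apply_filter(voiced, env)
  }
  silent_noise <- all(config$noise$envelope$anchors$value == -Inf)
  unvoiced <- if (silent_noise) waveform(numeric(0), sr)
              else generate_noise(config$noise, duration, sr, transfer = env)
  mix_voiced_unvoiced(voiced, unvoiced)
}

#' Synthesize a vocalization
#'
#' Runs the full pipeline: for each syllable, the voiced source (with
#' vibrato, jitter, shimmer, subharmonics and chaos gated by the nonlinear
#' regime track) and the turbulent noise component are generated, filtered
#' through the vocal-tract transfer function, and mixed; syllables are
#' concatenated with silent pauses, the bout optionally repeated, and the
#' result peak-normalized.  With a fixed `seed` the output is bit-identical
#' across calls; with `temperature > 0` and varying seeds each rendition
#' differs slightly, like repeated natural utterances.
#'
#' @param config a [synth_config()].
#' @param seed integer seed (defaults to `config$seed`); NULL draws from the
#'   current RNG stream.
#' @return a peak-normalized [waveform()].
#' @examples
#' w <- synthesize(synth_config(syllable_len = 150, temperature = 0.01,
#'                              seed = 1))
#' @export
synthesize <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  config <- apply_male_female(config)
  sr <- config$sampling_rate
  with_seed(seed, {
    pieces <- list()
    nb <- config$bout$n_syllables
    base_syl <- sample_contour(config$bout$syllable_len,
                               duration = 1, rate = nb)$values
    base_pau <- if (nb > 1)
      sample_contour(config$bout$pause_len, duration = 1,
                     rate = nb - 1L)$values else numeric(0)
    for (rep_i in seq_len(config$bout$repeat_bout)) {
      for (i in seq_len(nb)) {
        len_ms <- base_syl[i]
        if (config$temperature > 0)
          len_ms <- max(20, len_ms *
                          (1 + stats::rnorm(1, 0, 0.10 * config$temperature)))
        pieces[[length(pieces) + 1L]] <-
          synth_syllable(config, len_ms / 1000)$samples
        if (i < nb) {
          pau_ms <- base_pau[i]
          if (config$temperature > 0)
            pau_ms <- max(0, pau_ms *
                            (1 + stats::rnorm(1, 0,
                                              0.10 * config$temperature)))
          pieces[[length(pieces) + 1L]] <-
            numeric(as.integer(round(pau_ms / 1000 * sr)))
        }
      }
      if (rep_i < config$bout$repeat_bout) {
        gap_ms <- if (length(base_pau)) mean(base_pau) else 100
        pieces[[length(pieces) + 1L]] <-
          numeric(as.integer(round(gap_ms / 1000 * sr)))
      }
    }
    normalize_peak(waveform(unlist(pieces), sr))
  })
}

## ---- morphing -----------------------------------------------------------

lerp <- function(a, b, w) (1 - w) * a + w * b
gerp <- function(a, b, w) exp(lerp(log(a), log(b), w))  # geometric

## evaluate a contour at arbitrary normalized times
eval_contour_at <- function(spec, times) {
  a <- spec$anchors
  if (nrow(a) == 1L) return(rep(a$value, length(times)))
  y <- if (spec$scale == "log") log(a$value) else a$value
  v <- interp_monotone(a$time, y, times)
  if (spec$scale == "log") exp(v) else v
}

## interpolate two contour specs on the union of their anchor times
morph_contour <- function(ca, cb, w, rule = c("linear", "geometric")) {
  rule <- match.arg(rule)
  tt <- sort(unique(c(ca$anchors$time, cb$anchors$time)))
  va <- eval_contour_at(ca, tt)
  vb <- eval_contour_at(cb, tt)
  ## -Inf dB anchors (silence) are interpolated on a -96 dB floor
  va <- pmax(va, -96); vb <- pmax(vb, -96)
  vv <- if (rule == "geometric") gerp(va, vb, w) else lerp(va, vb, w)
  contour_spec(cbind(tt, vv), scale = ca$scale, parameter = ca$parameter,
               range = ca$range)
}

morph_formant_group <- function(ga, gb, w) {
  if (!identical(names(ga), names(gb)))
    stop("morph: formant tables are structurally incompatible",
         call. = FALSE)
  out <- ga
  for (nm in names(ga)) {
    out[[nm]]$freq <- morph_contour(ga[[nm]]$freq, gb[[nm]]$freq, w,
                                    "geometric")
    out[[nm]]$amp <- lerp(ga[[nm]]$amp, gb[[nm]]$amp, w)
    wa <- ga[[nm]]$width %||%
      estimate_bandwidth(mean(ga[[nm]]$freq$anchors$value))
    wb <- gb[[nm]]$width %||%
      estimate_bandwidth(mean(gb[[nm]]$freq$anchors$value))
    out[[nm]]$width <- if (is.null(ga[[nm]]$width) &&
                           is.null(gb[[nm]]$width)) NULL else lerp(wa, wb, w)
    out[[nm]]$strength <- lerp(ga[[nm]]$strength, gb[[nm]]$strength, w)
  }
  out
}

## one interior morph step at weight w (0 < w < 1)
morph_step <- function(a, b, w) {
  if (a$sampling_rate != b$sampling_rate)
    stop("morph: sampling rates differ", call. = FALSE)
  out <- a
  out$bout$n_syllables <- as.integer(round(lerp(a$bout$n_syllables,
                                                b$bout$n_syllables, w)))
  out$bout$repeat_bout <- as.integer(round(lerp(a$bout$repeat_bout,
                                                b$bout$repeat_bout, w)))
  out$bout$syllable_len <- morph_contour(a$bout$syllable_len,
                                         b$bout$syllable_len, w)
  out$bout$pause_len <- morph_contour(a$bout$pause_len, b$bout$pause_len, w)
  sa <- a$source; sb <- b$source; so <- sa
  so$f0 <- morph_contour(sa$f0, sb$f0, w, "geometric")
  so$ampl <- morph_contour(sa$ampl, sb$ampl, w)
  for (fld in c("rolloff", "vibrato_depth", "jitter_depth", "shimmer_depth",
                "attack_len", "am_depth", "am_shape", "sub_depth",
                "chaos_jitter", "chaos_shimmer"))
    so[[fld]] <- lerp(sa[[fld]], sb[[fld]], w)
  for (fld in c("vibrato_freq", "am_freq", "jitter_period"))
    so[[fld]] <- gerp(sa[[fld]], sb[[fld]], w)
  so$sub_ratio <- as.integer(round(lerp(sa$sub_ratio, sb$sub_ratio, w)))
  out$source <- so
  na_ <- a$noise; nb_ <- b$noise; no_ <- na_
  no_$envelope <- morph_contour(na_$envelope, nb_$envelope, w)
  no_$rolloff_noise <- lerp(na_$rolloff_noise, nb_$rolloff_noise, w)
  no_$flat_ceiling <- gerp(na_$flat_ceiling, nb_$flat_ceiling, w)
  if (!is.null(na_$own_filter) || !is.null(nb_$own_filter)) {
    if (is.null(na_$own_filter) || is.null(nb_$own_filter))
      stop("morph: only one config has a separate noise filter",
           call. = FALSE)
    no_$own_filter$formants <-
      morph_formant_group(na_$own_filter$formants, nb_$own_filter$formants, w)
  }
  out$noise <- no_
  out$formants$formants <-
    morph_formant_group(a$formants$formants, b$formants$formants, w)
  out$formants$antiformants <-
    morph_formant_group(a$formants$antiformants, b$formants$antiformants, w)
  ta <- a$tract; tb <- b$tract; to_ <- ta
  if (is.null(ta$vtl) != is.null(tb$vtl))
    stop("morph: vocal-tract length set in only one config", call. = FALSE)
  if (!is.null(ta$vtl)) to_$vtl <- gerp(ta$vtl, tb$vtl, w)
  to_$mouth <- morph_contour(ta$mouth, tb$mouth, w)
  to_$lip_radiation <- lerp(ta$lip_radiation, tb$lip_radiation, w)
  to_$nose_radiation <- lerp(ta$nose_radiation, tb$nose_radiation, w)
  out$tract <- to_
  for (fld in c("nonlinear_balance", "temperature", "male_female",
                "walk_smoothness"))
    out[[fld]] <- lerp(a[[fld]], b[[fld]], w)
  out
}

#' Interpolate between two synthesis configurations
#'
#' Produces a graded series of `n_steps` configurations from `config_a` to
#' `config_b`: frequencies (f0, formants, modulation rates) follow a
#' geometric rule, dB values and fractions a linear rule, integer counts are
#' rounded from the linear interpolant, and anchor contours are interpolated
#' after resampling both onto the union of their anchor times.  The first
#' element is exactly `config_a` and the last exactly `config_b`.  The two
#' configurations must be structurally compatible (same formant names, same
#' sampling rate).
#'
#' @param config_a,config_b [synth_config()] objects.
#' @param n_steps number of configurations to return (>= 2).
#' @return a list of `n_steps` `synth_config` objects.
#' @export
morph <- function(config_a, config_b, n_steps = 5) {
  stopifnot(inherits(config_a, "synth_config"),
            inherits(config_b, "synth_config"))
  if (n_steps < 2) stop("`n_steps` must be >= 2", call. = FALSE)
  w <- seq(0, 1, length.out = n_steps)
  out <- vector("list", n_steps)
  out[[1L]] <- config_a
  out[[n_steps]] <- config_b
  for (k in seq_len(n_steps)[-c(1L, n_steps)])
    out[[k]] <- morph_step(config_a, config_b, w[k])
  out
}
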