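## shared builders for the test-suite

## cheap voiced-only configuration (no filtering, no noise) for fast
## Monte-Carlo assertions
tonal_config <- function(f0 = 150, len_ms = 150, sr = 8000,
                         temperature = 0, seed = 1, ...) {
  synth_config(syllable_len = len_ms,
               source = source_params(f0 = f0, rolloff = 12,
                                      attack_len = 0),
               temperature = temperature, sampling_rate = sr,
               seed = seed, ...)
}

## manual regime track with an explicit label vector
manual_regimes <- function(labels, frame_rate = 100) {
  lv <- c("none", "subharmonics", "subharmonics+chaos")
  structure(list(labels = factor(labels, levels = lv),
                 frame_rate = frame_rate,
                 duration = length(labels) / frame_rate,
                 walk = rep(NA_real_, length(labels))),
            class = "regime_track")
}

## energy fraction of the Welch spectrum above a frequency
energy_above <- function(wave, freq) {
  ws <- vocsynth:::welch_spectrum(wave$samples, wave$sampling_rate, 1024)
  p <- 10 ^ (ws$power_db / 10)
  sum(p[ws$freq >= freq]) / sum(p)
}

## two-segment piecewise-linear (flat, then sloped) knee fit on a Welch
## spectrum, restricted to a band around the expected knee
fit_noise_knee <- function(wave, band = c(100, 3500),
                           candidates = c(400, 3000)) {
  ws <- vocsynth:::welch_spectrum(wave$samples, wave$sampling_rate, 1024)
  sel <- ws$freq >= band[1] & ws$freq <= band[2]
  f <- ws$freq[sel]; y <- ws$power_db[sel]
  cand <- f[f > candidates[1] & f < candidates[2]]
  sse <- vapply(cand, function(k) {
    x <- pmax(f - k, 0) / 1000
    sum(stats::resid(stats::lm(y ~ x)) ^ 2)
  }, 0)
  k <- cand[which.min(sse)]
  x <- pmax(f - k, 0) / 1000
  slope <- unname(stats::coef(stats::lm(y ~ x))[2])
  list(knee = k, slope = slope, bin_width = ws$bin_width,
       n_frames = ws$n_frames)
}

realize_formants_for_test <- function(ft, n) vocsynth:::realize_formants(ft, n)
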