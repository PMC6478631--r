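test_that("noise with zero slope and unity transfer is spectrally flat", {
  np <- noise_params(envelope = 0, rolloff_noise = 0)
  w <- generate_noise(np, 5, 22050, seed = 1)
  ws <- vocsynth:::welch_spectrum(w$samples, 22050, 1024)
  expect_gte(ws$n_frames, 200)
  band <- ws$freq > 200 & ws$freq < 10800
  lev <- ws$power_db[band]
  expect_lt(max(abs(lev - mean(lev))), 1.5)
})

test_that("noise length matches the duration contract", {
  np <- noise_params(envelope = 0)
  w <- generate_noise(np, 0.5, 22050, seed = 2)
  expect_lte(abs(length(w$samples) - 11025), 256)
})

test_that("spectral slope above the flat ceiling follows rolloff_noise", {
  np <- noise_params(envelope = 0, rolloff_noise = -6)
  w <- generate_noise(np, 5, 22050, seed = 3)
  ws <- vocsynth:::welch_spectrum(w$samples, 22050, 1024)
  ## 2-kHz span above the 1200-Hz ceiling: ~12 dB drop
  l2200 <- mean(ws$power_db[abs(ws$freq - 2200) < 60])
  l4200 <- mean(ws$power_db[abs(ws$freq - 4200) < 60])
  expect_equal(l2200 - l4200, 12, tolerance = 2)
  ## regression recovery of the slope itself
  sel <- ws$freq > 1400 & ws$freq < 10000
  slope <- unname(coef(lm(ws$power_db[sel] ~ I(ws$freq[sel] / 1000)))[2])
  expect_equal(slope, -6, tolerance = 1)
})

test_that("the flat region is unaffected by the high-frequency slope", {
  w0 <- generate_noise(noise_params(envelope = 0, rolloff_noise = 0),
                       5, 22050, seed = 4)
  w1 <- generate_noise(noise_params(envelope = 0, rolloff_noise = -12),
                       5, 22050, seed = 4)
  lev <- function(w) {
    ws <- vocsynth:::welch_spectrum(w$samples, 22050, 1024)
    mean(ws$power_db[ws$freq > 150 & ws$freq < 1100])
  }
  expect_lt(abs(lev(w0) - lev(w1)), 0.5)
})

test_that("noise synthesis is seeded and deterministic", {
  np <- noise_params(envelope = 0, rolloff_noise = -4)
  expect_identical(generate_noise(np, 1, 22050, seed = 11)$samples,
                   generate_noise(np, 1, 22050, seed = 11)$samples)
})

test_that("voiced/unvoiced mixing is additive and supports voiceless output", {
  sr <- 8000
  v <- waveform(sin(2 * pi * 200 * (0:799) / sr), sr)
  silent <- waveform(numeric(800), sr)
  empty <- waveform(numeric(0), sr)
  expect_equal(mix_voiced_unvoiced(v, silent)$samples, v$samples)
  n <- waveform(runif(800, -0.5, 0.5), sr)
  expect_equal(mix_voiced_unvoiced(empty, n)$samples, n$samples)
  rms <- function(x) sqrt(mean(x ^ 2))
  mixed <- mix_voiced_unvoiced(v, n)
  expect_lte(rms(mixed$samples), rms(v$samples) + rms(n$samples))
  ## offsets shift placement
  off <- mix_voiced_unvoiced(v, n, alignment = c(0, 0.05))
  expect_equal(length(off$samples), 800 + 0.05 * sr)
  expect_error(mix_voiced_unvoiced(v, waveform(runif(10), 16000)),
               "sampling rates")
})
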