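test_that("durations add up: syllables plus pauses within one STFT hop", {
  cfg1 <- synth_config(syllable_len = 300, temperature = 0,
                       tract = tract_params(vtl = 17.7), seed = 1)
  w1 <- synthesize(cfg1)
  expect_lte(abs(length(w1$samples) - round(0.3 * 22050)), 256)
  cfg3 <- synth_config(n_syllables = 3, syllable_len = 200, pause_len = 100,
                       temperature = 0, tract = tract_params(vtl = 17.7),
                       seed = 1)
  w3 <- synthesize(cfg3)
  expect_lte(abs(length(w3$samples) - round(0.8 * 22050)), 3 * 256)
})

test_that("synthesis is bit-deterministic and peak-normalized", {
  cfg <- synth_config(syllable_len = 250, temperature = 0.05,
                      source = source_params(f0 = c(150, 120),
                                             jitter_depth = 0.2,
                                             shimmer_depth = 0.05),
                      noise = noise_params(envelope = -20),
                      tract = tract_params(vtl = 16), seed = 42,
                      nonlinear_balance = 0.4)
  a <- synthesize(cfg); b <- synthesize(cfg)
  expect_identical(a$samples, b$samples)
  expect_gte(max(abs(a$samples)), 0.99)
  expect_lte(max(abs(a$samples)), 1.0)
  ## different seeds give different renditions when temperature > 0
  expect_false(identical(synthesize(cfg, seed = 1)$samples,
                         synthesize(cfg, seed = 2)$samples))
})

test_that("syllable length varies with SD proportional to temperature", {
  lens <- function(temp) {
    cfg <- tonal_config(len_ms = 150, sr = 8000, temperature = temp)
    vapply(1:200, function(s) length(synthesize(cfg, seed = s)), 0L)
  }
  l_lo <- lens(0.05); l_hi <- lens(0.2)
  expect_gt(sd(l_hi), sd(l_lo))
  ## SD ~ temperature * 10% of the 1200-sample syllable
  expect_equal(sd(l_hi), 0.2 * 0.10 * 1200, tolerance = 0.3)
  expect_equal(sd(l_hi) / sd(l_lo), 4, tolerance = 0.5)
})

test_that("maleFemale shifts f0 and vocal tract in a coordinated way", {
  cfg <- synth_config(source = source_params(f0 = c(200, 150)),
                      formants = formant_table(list(f1 = 500)),
                      tract = tract_params(vtl = 17.7), male_female = 0)
  expect_identical(apply_male_female(cfg), cfg)
  cfg$male_female <- 1
  m <- apply_male_female(cfg)
  expect_equal(m$source$f0$anchors$value, c(100, 75))
  expect_equal(m$tract$vtl, 17.7 * 1.25)
  expect_equal(m$formants$formants$f1$freq$anchors$value, 500 / 1.25)
  ## monotone: f0 non-increasing across the whole axis
  f0_at <- vapply(seq(-1, 1, length.out = 21), function(mf) {
    cfg$male_female <- mf
    max(apply_male_female(cfg)$source$f0$anchors$value)
  }, 0)
  expect_true(all(diff(f0_at) <= 1e-12))
})

test_that("morphing interpolates geometrically for frequencies with exact endpoints", {
  a <- synth_config(source = source_params(f0 = 100), seed = 1)
  b <- synth_config(source = source_params(f0 = 200), seed = 1)
  expect_identical(morph(a, b, 2), list(a, b))
  mid <- morph(a, b, 3)[[2]]
  expect_equal(mid$source$f0$anchors$value, sqrt(100 * 200),
               tolerance = 1e-12)
  ## degenerate morph: identical endpoints give identical steps
  steps <- morph(a, a, 4)
  for (s in steps) expect_equal(s$source$f0$anchors$value, 100)
  ## endpoint fidelity through synthesis
  expect_identical(synthesize(morph(a, b, 5)[[1]], seed = 3)$samples,
                   synthesize(a, seed = 3)$samples)
  ## incompatible formant structure is refused
  c2 <- synth_config(formants = formant_table(list(f1 = 500)))
  expect_error(morph(a, c2, 3), "incompatible")
})
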