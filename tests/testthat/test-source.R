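test_that("vibrato modulates f0 sinusoidally with the stated depth", {
  sr <- 8000
  ## no vibrato, no jitter: constant track
  p0 <- source_params(f0 = 100)
  expect_equal(compute_f0_track(p0, 1, sr), rep(100, sr))
  ## 1 semitone at 5 Hz: extrema at 100 * 2^(+-1/12)
  p1 <- source_params(f0 = 100, vibrato_depth = 1, vibrato_freq = 5)
  tr <- compute_f0_track(p1, 1, sr)
  expect_equal(max(tr), 100 * 2 ^ (1 / 12), tolerance = 1e-6)
  expect_equal(min(tr), 100 * 2 ^ (-1 / 12), tolerance = 1e-6)
  ## 5 cycles per second
  up_cross <- sum(diff(tr > 100) == 1)
  expect_equal(up_cross, 5, tolerance = 0.21)
})

test_that("jitter has the configured semitone SD and is seeded", {
  sr <- 22050
  p <- source_params(f0 = 100, jitter_depth = 0.5, jitter_period = 0.02)
  tr <- compute_f0_track(p, 0.5, sr, seed = 9)
  dev_st <- 12 * log2(tr / 100)
  expect_equal(sd(dev_st), 0.5, tolerance = 0.1 * 0.5)
  expect_identical(tr, compute_f0_track(p, 0.5, sr, seed = 9))
})

test_that("harmonic amplitudes follow the exponential rolloff law", {
  p <- source_params(rolloff = 12)
  expect_equal(harmonic_amplitudes(1, 100, p), 1.0)
  expect_equal(harmonic_amplitudes(2, 100, p), 10 ^ (-12 / 20),
               tolerance = 1e-12)
  p6 <- source_params(rolloff = 6)
  expect_equal(harmonic_amplitudes(4, 100, p6), 10 ^ (-12 / 20),
               tolerance = 1e-12)
  expect_error(harmonic_amplitudes(0, 100, p), ">= 1")
  ## measured slope of a synthesized flat-pitch source ~ -rolloff
  w <- synthesize_voiced(rep(200, 44100),
                         source_params(f0 = 200, rolloff = 12,
                                       attack_len = 0), 22050)
  m <- measure_peaks_and_rolloff(w, f0_hint = 200)
  expect_equal(m$rolloff_slope, -12, tolerance = 1)
})

test_that("additive synthesis matches the closed-form sine and Nyquist rule", {
  ## single audible harmonic, zero phase: quarter period of a 100-Hz tone at
  ## 8 kHz is sample 20
  p <- source_params(f0 = 100, rolloff = 1000, attack_len = 0)
  w <- synthesize_voiced(rep(100, 8000), p, 8000)
  expect_equal(w$samples[20], 1.0, tolerance = 1e-6)
  ## silent amplitude envelope => silent output
  pz <- source_params(f0 = 100, ampl = -Inf, attack_len = 0)
  expect_equal(max(abs(synthesize_voiced(rep(100, 800), pz, 8000)$samples)), 0)
  ## exactly 27 harmonics at f0 = 400 Hz, 22050 Hz
  expect_identical(harmonic_count(400, 22050), 27L)
  plan <- add_subharmonics(source_params(f0 = 400), rep(400, 100), 22050)
  expect_identical(nrow(plan), 27L)
  ## no spectral energy above Nyquist - 50 Hz
  w2 <- synthesize_voiced(rep(400, 22050),
                          source_params(f0 = 400, rolloff = 3,
                                        attack_len = 0), 22050)
  expect_lt(energy_above(w2, 22050 / 2 - 50), 0.01)
  expect_error(synthesize_voiced(c(100, -1), p, 8000), "positive")
})

test_that("subharmonics appear at multiples of g0 between the harmonics", {
  plan <- add_subharmonics(source_params(f0 = 200, sub_ratio = 2,
                                         sub_depth = 6),
                           rep(200, 100), 2000)
  subs <- plan$mult[plan$sub]
  expect_equal(subs, c(0.5, 1.5, 2.5, 3.5, 4.5))
  ## infinitely deep sidebands = no subharmonics at all
  p_inf <- source_params(f0 = 200, sub_ratio = 2, sub_depth = Inf,
                         attack_len = 0)
  p_off <- source_params(f0 = 200, sub_ratio = 1, attack_len = 0)
  expect_equal(synthesize_voiced(rep(200, 4000), p_inf, 8000)$samples,
               synthesize_voiced(rep(200, 4000), p_off, 8000)$samples)
  ## spectral peaks of a k = 3 synthesis are spaced f0/3
  sp <- source_params(f0 = 300, rolloff = 6, sub_ratio = 3, sub_depth = 6,
                      attack_len = 0)
  w <- synthesize_voiced(rep(300, 44100), sp, 22050)
  m <- measure_peaks_and_rolloff(w, n_fft = 8192, prominence_db = 6)
  pk <- m$peaks$freq[m$peaks$freq > 50 & m$peaks$freq < 1500]
  expect_equal(median(diff(pk)), 100, tolerance = m$bin_width / 100)
})

test_that("the nonlinear regime walk respects its balance and thresholds", {
  r0 <- generate_regime_track(1, nonlinear_balance = 0, seed = 3)
  expect_true(all(r0$labels == "none"))
  r1 <- generate_regime_track(1, nonlinear_balance = 1, seed = 3)
  expect_true(all(r1$labels == "subharmonics+chaos"))
  ra <- generate_regime_track(2, 0.5, seed = 7)
  rb <- generate_regime_track(2, 0.5, seed = 7)
  expect_identical(ra$labels, rb$labels)
  expect_error(generate_regime_track(1, 0.5, thresholds = c(0.9, 0.2)),
               "increasing")
})

test_that("chaos frames carry stronger jitter than tonal frames", {
  p <- source_params(f0 = 150, jitter_depth = 0.05, jitter_period = 0.01,
                     chaos_jitter = 1.5)
  ## no chaos frames: depths stay at baseline
  r_none <- manual_regimes(rep("none", 20))
  expect_true(all(apply_chaos(p, r_none)$jitter_track == 0.05))
  r_all <- manual_regimes(rep("subharmonics+chaos", 20))
  expect_true(all(apply_chaos(p, r_all)$jitter_track == 1.5))
  ## half-chaos: paired comparison of semitone SD across 100 seeds
  sr <- 8000
  reg <- manual_regimes(rep(c("none", "subharmonics+chaos"), each = 10))
  pc <- apply_chaos(p, reg)
  sds <- vapply(1:100, function(s) {
    tr <- compute_f0_track(pc, 0.2, sr, seed = s)  # 1600 samples
    dev <- 12 * log2(tr / 150)
    c(sd(dev[1:800]), sd(dev[801:1600]))
  }, c(0, 0))
  expect_gt(mean(sds[2, ]), mean(sds[1, ]))
  expect_gt(mean(sds[2, ] > sds[1, ]), 0.9)
})

test_that("voiced synthesis is bit-deterministic given (config, seed)", {
  p <- source_params(f0 = 180, jitter_depth = 0.3, shimmer_depth = 0.1)
  tr <- compute_f0_track(p, 0.3, 22050, seed = 5)
  a <- synthesize_voiced(tr, p, 22050, seed = 5)
  b <- synthesize_voiced(tr, p, 22050, seed = 5)
  expect_identical(a$samples, b$samples)
})
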