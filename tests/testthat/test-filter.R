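test_that("uniform-tube formant formulas and VTL estimation invert exactly", {
  expect_equal(formant_frequencies_from_vtl(17.7, 3), c(500, 1500, 2500))
  expect_equal(diff(formant_frequencies_from_vtl(17.7, 6)),
               rep(1000, 5))  # dispersion d = c/(2 VTL)
  expect_equal(formant_frequencies_from_vtl(17.7, 1), 35400 / (4 * 17.7))
  expect_equal(estimate_vtl(c(500, 1500, 2500)), 17.7)
  expect_equal(estimate_vtl(500), 17.7)
  expect_equal(estimate_vtl(2 * c(500, 1500, 2500)), 17.7 / 2)
  expect_error(estimate_vtl(numeric(0)), "positive")
  expect_error(formant_frequencies_from_vtl(-1, 3), "vtl")
  ## round trip across tract lengths
  for (L in seq(5, 100, by = 5))
    expect_equal(estimate_vtl(formant_frequencies_from_vtl(L, 4)), L,
                 tolerance = 1e-9)
})

test_that("tube formants are appended above user formants up to Nyquist", {
  ft <- formant_table(list(f1 = 500, f2 = 1500))
  ext <- extend_formants(ft, vtl = 17.7, nyquist = 11025)
  freqs <- vapply(ext$formants, function(f) f$freq$anchors$value[1], 0)
  expect_equal(unname(freqs), c(500, 1500, seq(2500, 10500, by = 1000)))
  ## user formants already at Nyquist: unchanged
  ft2 <- formant_table(list(f1 = 11000))
  expect_length(extend_formants(ft2, vtl = 1.61, nyquist = 11025)$formants, 1L)
  ## empty table + VTL: full schwa series
  schwa <- extend_formants(formant_table(), vtl = 17.7, nyquist = 11025)
  expect_equal(unname(vapply(schwa$formants,
                             function(f) f$freq$anchors$value[1], 0)),
               seq(500, 10500, by = 1000))
  ## temperature exactly zero disables the extension
  expect_length(extend_formants(ft, vtl = 17.7, nyquist = 11025,
                                temperature = 0)$formants, 2L)
})

test_that("mouth opening shifts formants linearly; closure nasalizes", {
  vtl <- 17.7
  ft <- formant_table(list(f1 = 500, f2 = 1500, f3 = 2500))
  mscan <- seq(0, 1, by = 0.05)
  fr <- adjust_for_mouth(realize_formants_for_test(ft, length(mscan)),
                         mscan, vtl)
  shifts <- fr$poles$freq[1, ] - 500
  ## dF = (m - 0.5) c / (4 VTL): 0 at neutral, +-250 Hz at the extremes
  expect_equal(shifts[mscan == 0.5], 0)
  expect_equal(shifts[mscan == 1], 250)
  expect_equal(shifts[mscan == 0], -250)
  expect_equal(shifts, (mscan - 0.5) * 35400 / (4 * vtl))
  ## identical shift for every formant at a given frame
  expect_equal(fr$poles$freq[2, 1:21] - 1500, shifts)
  expect_equal(fr$poles$freq[3, 1:21] - 2500, shifts)
  ## closed mouth: B1 = 175 Hz plus a zero-pole pair near F1
  closed <- which(mscan == 0)
  expect_equal(fr$poles$width[1, closed], 175)
  expect_equal(nrow(fr$zeros$freq), 1L)   # inserted zero
  expect_false(is.na(fr$zeros$freq[1, closed]))
  expect_true(all(is.na(fr$zeros$freq[1, -closed])))
  expect_equal(fr$zeros$freq[1, closed], (500 - 250) - 100)
  expect_error(adjust_for_mouth(ft, rep(1.5, 3), vtl), "\\[0, 1\\]")
})

test_that("bandwidth estimation is positive, corrected at low frequency", {
  expect_true(all(estimate_bandwidth(c(100, 300, 500, 1000, 3000)) > 0))
  ## the sub-500-Hz correction widens low-frequency bandwidths
  grid <- seq(50, 500, by = 25)
  bw <- estimate_bandwidth(grid)
  expect_true(all(diff(bw) <= 0))
  expect_gt(estimate_bandwidth(200), estimate_bandwidth(500))
  expect_error(estimate_bandwidth(-10), "positive")
  ## user-specified bandwidth is honoured end-to-end
  ft <- formant_table(list(f1 = list(freq = 500, width = 99)))
  fr <- vocsynth:::fill_bandwidths(
    vocsynth:::realize_formants(ft, 3))
  expect_equal(fr$poles$width[1, ], rep(99, 3))
})

test_that("the spectral envelope has poles at formants and exact pole-zero cancellation", {
  geom <- vocsynth:::stft_geometry(22050, 4)
  ## empty table, zero radiation: unity
  env0 <- compute_spectral_envelope(formant_table(), geom,
                                    tract_params(lip_radiation = 0))
  expect_equal(env0$gain, matrix(1, nrow(env0$gain), 4))
  ## single formant peaks in the bin containing it
  env1 <- compute_spectral_envelope(
    formant_table(list(f1 = list(freq = 500, width = 50))), geom,
    tract_params(lip_radiation = 0))
  pk <- env1$freqs[which.max(env1$gain[, 1])]
  expect_lt(abs(pk - 500), 22050 / 1024)
  ## pole and zero at the same place cancel to a flat envelope
  env2 <- compute_spectral_envelope(
    formant_table(list(f1 = list(freq = 800, width = 80)),
                  antiformants = list(af1 = list(freq = 800, width = 80))),
    geom, tract_params(lip_radiation = 0))
  expect_lt(max(abs(20 * log10(env2$gain))), 0.1)
  expect_error(compute_spectral_envelope(
    formant_table(list(f1 = list(freq = 500, width = 0))), geom), "> 0")
})

test_that("spectrogram filtering reconstructs, silences, and is linear", {
  sr <- 22050
  set.seed(1)
  x <- waveform(runif(sr / 2, -0.5, 0.5), sr)
  nfr <- vocsynth:::stft_n_frames(length(x$samples))
  geom <- vocsynth:::stft_geometry(sr, nfr)
  unity <- compute_spectral_envelope(formant_table(), geom,
                                     tract_params(lip_radiation = 0))
  y <- apply_filter(x, unity)
  expect_equal(length(y$samples), length(x$samples))
  rel_err <- sqrt(mean((y$samples - x$samples) ^ 2) / mean(x$samples ^ 2))
  expect_lt(rel_err, 1e-3)
  ## zero envelope silences
  zero <- unity; zero$gain[] <- 0
  expect_equal(max(abs(apply_filter(x, zero)$samples)), 0)
  ## linearity
  x2 <- waveform(sin(2 * pi * 330 * seq_len(sr / 2) / sr), sr)
  f1 <- compute_spectral_envelope(
    formant_table(list(f1 = list(freq = 2000, width = 100))), geom,
    tract_params(lip_radiation = 0))
  lhs <- apply_filter(waveform(2 * x$samples + 3 * x2$samples, sr), f1)
  rhs <- 2 * apply_filter(x, f1)$samples + 3 * apply_filter(x2, f1)$samples
  expect_equal(lhs$samples, rhs, tolerance = 1e-10)
  ## white noise through a 2-kHz formant peaks at 2 kHz
  filt <- apply_filter(x, f1)
  ws <- vocsynth:::welch_spectrum(filt$samples, sr, 1024)
  expect_lt(abs(ws$freq[which.max(ws$power_db)] - 2000), 2 * ws$bin_width)
})

test_that("synthesized formants are recovered from the output spectrum", {
  targets <- c(700, 1200, 2600)
  cfg <- synth_config(
    syllable_len = 500,
    source = source_params(f0 = 100, rolloff = 3, attack_len = 0.005),
    formants = formant_table(list(f1 = 700, f2 = 1200, f3 = 2600)),
    temperature = 0.001, seed = 2)
  w <- synthesize(cfg)
  ws <- vocsynth:::welch_spectrum(w$samples, w$sampling_rate, 2048)
  for (f in targets) {
    sel <- abs(ws$freq - f) <= 220
    got <- ws$freq[sel][which.max(ws$power_db[sel])]
    expect_lt(abs(got - f), 50)
  }
})
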