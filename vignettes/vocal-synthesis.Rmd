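---
title: "How vocsynth synthesizes nonverbal vocalizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How vocsynth synthesizes nonverbal vocalizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocsynth)
```

`vocsynth` is a parametric vocoder for nonverbal vocalizations — moans,
screams, laugh syllables, roars, and comparable animal calls. It follows the
source–filter view of vocal production: an excitation produced at the glottis
(or syrinx) is shaped by the resonances of the vocal tract. Unlike
speech-oriented vocoders that model individual glottal pulses in the time
domain, the source here is defined spectrally, which makes it equally
comfortable with modal voice, high-pitched screams, and the dense sideband
spectra of nonlinear phenomena, and lets every perceptually relevant control
act directly on the spectrum.

## Sparse control: anchor contours

Every time-varying parameter (f0, amplitude, mouth opening, formant
frequencies) is specified as a handful of `[time, value]` anchors with time
normalized to `[0, 1]` over the segment the contour governs. Densification
uses shape-preserving monotone cubic (PCHIP) interpolation: the curve passes
exactly through the anchors and cannot overshoot between them, so a pitch
contour specified as rise–fall never rings. Strictly positive quantities
(f0, formant frequencies) are interpolated on the log scale, which is
perceptually uniform for pitch; amplitudes in dB and the mouth contour are
interpolated linearly. Normalizing anchor time per segment means the same
contour serves syllables of any length — important because the temperature
hyperparameter may stretch syllables stochastically.

## The voiced source

The voiced excitation is an additive stack of sine-wave harmonics. With
sampling rate $s$ and per-sample fundamental $f_0(t)$, harmonic $h$
contributes

$$w_h(t) = a_h(t)\,\sin\!\Big(2\pi \tfrac{h}{s} \sum_{u=1}^{t} f_0(u)\Big),$$

with zero initial phase; the waveform is the sum over $h$. No component is
ever generated above the Nyquist frequency: samples where $h\,f_0(t) > s/2$
contribute zero, so at $f_0 = 400$ Hz and $s = 22050$ Hz exactly 27
harmonics exist. Harmonic amplitudes follow an exponential source spectrum,
$a_h = 10^{-\text{rolloff}\,\log_2 h / 20}$ — each octave above the
fundamental loses `rolloff` dB — with an optional user hook for
non-exponential source shapes.

Modulations of this stack:

* **Vibrato** — a deterministic factor
  $2^{\,d \sin(2\pi f_v t)/12}$ (depth $d$ in semitones, rate $f_v$ in Hz).
* **Jitter** — stochastic pitch fluctuation on the semitone scale. A
  Gaussian sequence is smoothed by a moving average of width
  `jitter_period` seconds and then renormalized to unit variance, so the
  realized semitone SD equals `jitter_depth` exactly rather than only in
  expectation; short periods give rough, fast fluctuation, long periods a
  slow wander.
* **Shimmer** — cycle-to-cycle amplitude perturbation. Cycle boundaries are
  read off the cumulative phase of the fundamental, and each cycle receives
  a multiplicative factor $1 + z\,\sigma$ ($z$ standard normal, $\sigma$ =
  `shimmer_depth`), clamped to $[0.05, 2]$.
* **Low-frequency amplitude modulation** for trill-like sounds:
  depth, rate, and a shape exponent that sharpens the troughs.
* **Attack** — a raised-cosine fade of `attack_len` seconds at both edges.

## Nonlinear vocal phenomena

Subharmonics introduce a second fundamental $g_0 = f_0/k$ with integer
`sub_ratio` $k$: sinusoids are added at multiples of $g_0$ that are not
multiples of $f_0$, at `sub_depth` dB below the harmonic envelope
interpolated at their frequency (below $f_0$ the envelope is clamped at the
fundamental's amplitude). The sideband level is uniform relative to the
local envelope — the simplest defensible profile, and exposed in the
configuration. Deterministic chaos is simulated as strong jitter plus
strong shimmer (defaults 1.5 semitones and 25%, both configurable).

Where these effects occur over time is governed by a seeded random walk:
Gaussian increments are accumulated, reflected into $[0,1]$, smoothed by a
moving average of `walk_smoothness` frames, then shifted by
$2(\text{balance} - 0.5)$ and clamped. Values below the first threshold
(default 0.5) mean no nonlinear effects, values between the thresholds
enable subharmonics, and values above the second (default 0.8) enable
subharmonics plus chaos. `nonlinear_balance = 0` therefore forces a purely
tonal sound and `1` chaos throughout, with unpredictable regime transitions
in between. Baseline jitter and shimmer apply in all frames; chaos frames
raise them to the chaos levels.

## The unvoiced source

Turbulent noise is built directly in the frequency domain: per STFT frame,
one-sided magnitudes are drawn i.i.d. uniform on $[0,1]$ (the most literal
reading of spectral-domain noise; drawing uniform dB would be an
alternative, and the choice only shifts the distribution of frame-to-frame
level fluctuations), multiplied by the source shape — flat up to
`flat_ceiling` (default 1200 Hz), then a linear slope of `rolloff_noise`
dB/kHz — and by the vocal-tract transfer function, given uniform random
phases, and overlap-added back to a waveform. Noise carries its own
amplitude envelope, independent of the voiced envelope, and may carry its
own filter (for non-glottal noises such as hissing); by default it passes
through the same vocal tract as the voiced component, and a configuration
with `voiced: false` yields purely voiceless synthesis.

## The filter

All spectral operations share one STFT geometry: 1024-sample periodic Hann
frames with 75% overlap. At that hop the squared window overlap-adds to the
constant 3/2, so analysis–multiply–resynthesis reconstructs a signal to
floating-point accuracy (the ends are zero-padded by one frame so edge
samples get full window coverage).

The transfer function is a gain matrix over bins × frames. Per frame, each
formant contributes the magnitude response of a second-order resonance with
unit gain at DC:

$$|T_i(f)| = \frac{\sigma_i^2 + \omega_i^2}
 {\sqrt{(\sigma_i^2 + (\omega - \omega_i)^2)\,(\sigma_i^2 + (\omega + \omega_i)^2)}},
 \qquad \sigma_i = \pi B_i,\ \omega_i = 2\pi F_i,$$

and the envelope is the product over formants divided by the corresponding
terms for antiformants (zeros). A per-formant `strength` exponent on the
resonance term and a per-formant `amp` (dB, applied around the peak) give
flexible control over individual formant levels. Lip and nose radiation are
separate spectral tilts in dB/octave (defaults +6 and 0, referenced to 500
Hz) rather than being folded into the source spectrum, which makes
non-human configurations easy.

Formant series derive from the uniform-tube model: a tube of length
$\mathrm{VTL}$ closed at the glottis resonates at
$F_n = (2n-1)\,c/(4\,\mathrm{VTL})$ with constant dispersion
$d = c/(2\,\mathrm{VTL})$, where $c = 35{,}400$ cm/s is the speed of sound
in warm air. Given user formants, apparent VTL is estimated by regression
through the origin of $F_i$ on $(2i-1)$ — the exact inverse of the tube
formula on clean input — and tube formants are appended above the highest
user formant up to Nyquist. Setting temperature exactly to zero disables
this extension, which is why a small positive temperature is recommended
for precise work.

Mouth opening $m \in [0,1]$ shifts every formant by
$\Delta F = (m - 0.5)\,c/(4\,\mathrm{VTL})$: nothing at the neutral 0.5,
−250 Hz fully closed and +250 Hz fully open for a 17.7-cm tract. At frames
where the mouth is fully closed the output is nasalized: the first
formant's bandwidth is set to 175 Hz and a zero–pole pair is inserted near
F1 (zero at $F_1 - 100$ Hz, pole at $F_1 + 100$ Hz, both 100 Hz wide —
constants appropriate for human voice and config-exposed). Where the user
gives no bandwidth it is estimated from frequency by this package's own
empirical curve, $B = 50\,(1 + (f/2500)^2)$ Hz above 500 Hz, widened below
500 Hz by $B(500)\,(1 + 2((500-f)/500)^2)$ — continuous, positive, and
non-increasing toward 500 Hz from below, reflecting the phonetic
observation that very low formants are broad. Any user-supplied bandwidth
overrides it.

## Assembly, hyperparameters, output

Syllables are synthesized independently and concatenated with silent pauses
of the specified lengths; no smoothing is applied across boundaries, which
matches how polysyllabic calls are naturally built from repeated glottal
gestures. `temperature` scales all stochastic variation with per-parameter
scales fixed in one table (5% of value for f0 and formant frequencies, 2 dB
for amplitudes, 10% for syllable and pause lengths, 0.05 for mouth
opening); zero temperature plus a fixed seed gives bit-identical output.
`male_female` shifts f0 by $2^{-mf}$ and VTL by $1.25^{mf}$ in one
coordinated move, implemented through VTL so tube-extended formants stay
consistent. The final waveform is normalized to peak 0.995 (−0.04 dBFS) —
full peak normalization with a small guard against quantization clipping —
and written as 16-bit mono PCM WAV, by convention at 22050 Hz.

`morph()` produces graded series between two configurations: geometric
interpolation for frequencies, linear for dB values and fractions, rounding
for integer counts, and anchor contours interpolated after resampling both
onto the union of their anchor times. Endpoints are returned verbatim, so
step 1 synthesizes bit-identically to the first configuration. Morphing
requires structurally compatible configurations (same formant names, same
sampling rate); reconciling different structures is deliberately left to
the user.

## Verification

The package measures its own output. The f0 tracker computes a per-frame
autocorrelation via FFT, corrects the linear taper of the finite window
(the "unbiased" estimate), and — because that correction makes peaks at
integer multiples of the true period equally strong — picks the shortest
lag among near-maximal local peaks, with parabolic interpolation for
sub-sample resolution. Frames whose peak autocorrelation falls below 0.45
are flagged unvoiced; spectral peak picking requires 10 dB of prominence.
Both thresholds live in the exported `verify_constants` table so every
measurement in the test-suite is reproducible. Source rolloff is recovered
by regressing harmonic peak level (dB) on $\log_2 h$ over the
Welch-averaged spectrum; the noise knee by fitting a flat-then-sloped
two-segment model over the 100–3500 Hz band (restricting the band keeps
the far spectral tail, where window leakage dominates, out of the fit).

These estimators are test oracles for self-synthesized signals, not
general-purpose audio analysis: the tracker assumes clean, near-harmonic
input, and nothing here competes with a dedicated pitch tracker on real
recordings.

## Numerical choices and problem sizes

Monte-Carlo checks in the test-suite use sizes chosen to make the measured
quantities stable at their stated tolerances: 10,000 draws for perturbation
SDs, 200 noise frames (5–10 s at 22050 Hz) for spectral-slope and knee
estimates, 100 random tonal configurations (0.4 s at 16 kHz) for tracker
calibration, and 100 paired seeds for the chaos-versus-tonal comparison.
Cheap configurations without filtering or noise are used where only timing
or lengths are being measured.

What the synthetic tests do not show: passing them demonstrates the
synthesis pipeline realizes its own stated acoustics (formant positions,
rolloff slopes, subharmonic spacing, determinism), not that any particular
configuration sounds natural to human listeners — perceived naturalness
and emotional content are empirical questions about listeners, outside the
package's scope.

## Known limitations

* No glottal-pulse (time-domain) excitation mode; the source is strictly
  spectral, so features tied to pulse shape (e.g. a specific open quotient)
  cannot be expressed directly.
* No articulatory modeling: formants are specified or tube-derived, not
  computed from tract geometry; consonants and rapid formant transitions of
  speech are out of scope.
* Synthesis is not real time; the design optimizes controllability, not
  throughput.
* The closed-mouth nasalization constants are appropriate for human voice;
  for animal calls, specify the corresponding formant transitions manually
  instead of closing the mouth.
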