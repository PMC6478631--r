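# voiced laugh syllables with aspiration between them
bout:
  n_syllables: 4
  syllable_len: [[0, 160], [1, 110]]
  pause_len: 130
source:
  f0: [[0, 290], [0.5, 260], [1, 230]]
  ampl: [[0, 0], [1, -4]]
  rolloff: 9
  attack_len: 0.015
noise:
  envelope: [[0, -20], [1, -14]]
  rolloff_noise: -6
tract:
  vtl: 15
formants:
  f1: {freq: 700}
  f2: {freq: 1400}
  f3: {freq: 2600}
temperature: 0.1
seed: 13
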