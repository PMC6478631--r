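# breathy low-pitched moan, single long syllable
bout:
  syllable_len: 700
source:
  f0: [[0, 150], [0.3, 165], [1, 110]]
  ampl: [[0, 0], [1, -6]]
  rolloff: 12
  attack_len: 0.04
noise:
  envelope: [[0, -25], [1, -18]]
  rolloff_noise: -8
tract:
  vtl: 15.5
formants:
  f1: {freq: 630}
  f2: {freq: 1150}
  f3: {freq: 2500}
temperature: 0.05
seed: 11
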