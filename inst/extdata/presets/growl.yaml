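# animal-like growl: long tract, deep f0, dense subharmonics, trill-like AM
bout:
  syllable_len: 800
source:
  f0: [[0, 95], [0.5, 105], [1, 85]]
  rolloff: 9
  sub_ratio: 3
  sub_depth: 6
  jitter_depth: 0.5
  jitter_period: 0.03
  am_depth: 0.35
  am_freq: 22
  am_shape: 2
  attack_len: 0.06
noise:
  envelope: [[0, -28], [1, -24]]
  rolloff_noise: -12
nonlinear_balance: 0.85
tract:
  vtl: 25
  mouth: 0.35
temperature: 0.05
seed: 15
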