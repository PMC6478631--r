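# harsh human roar: subharmonics and chaos over most of the call
bout:
  syllable_len: 1200
source:
  f0: [[0, 170], [0.4, 220], [1, 150]]
  rolloff: 6
  jitter_depth: 0.4
  shimmer_depth: 0.12
  sub_ratio: 2
  sub_depth: 8
  attack_len: 0.05
noise:
  envelope: [[0, -22], [1, -22]]
  rolloff_noise: -10
nonlinear_balance: 0.75
tract:
  vtl: 19
  mouth: [[0, 0.5], [0.5, 1.0], [1, 0.4]]
temperature: 0.05
seed: 14
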