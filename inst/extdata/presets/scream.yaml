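# high-pitched scream with rough (chaotic) episodes
bout:
  syllable_len: 900
source:
  f0: [[0, 550], [0.35, 900], [1, 520]]
  rolloff: 6
  jitter_depth: 0.3
  jitter_period: 0.008
  shimmer_depth: 0.1
  attack_len: 0.02
  chaos_jitter: 1.2
  chaos_shimmer: 0.3
nonlinear_balance: 0.55
tract:
  vtl: 14
  mouth: [[0, 0.4], [0.3, 0.9], [1, 0.5]]
temperature: 0.05
seed: 12
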