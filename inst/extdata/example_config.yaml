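# Oscillating-environment run: the pure-competition-with-synergy scenario.
rates:
  r_A: 1.8
  r_B: 1.0
  a_AA: 0.1
  a_AB: 0.1
  a_BA: 0.1
  a_BB: 0.1
  gamma: 0.0
environment:
  omega: 5
  oscillations:
    - {target: rA, k: 1, cos: -1.6, sin: 0.0}
    - {target: rB, k: 1, cos: 1.6, sin: 0.0}
    - {target: gamma, k: 1, cos: 0.0, sin: 0.5}
init:
  p_A: 0.5
  'N': 1.0
run:
  t_end: 60
  n_per_period: 40
  seed: 1
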