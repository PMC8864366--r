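# Example sweep config for `kinevo sweep`: a coarse 2 x 2 phase grid
# at reduced scale. `base` keys mirror kin_params() (d_c/d_m come from
# the grid).
d_c: [0.3, 0.5]
d_m: [0.2, 1.0]
n_trials: 5
base_seed: 1
base:
  N_f: 15
  N_s: 10
  n_steps: 150
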