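# Example simulation config for `kinevo simulate`
# Keys mirror the arguments of kin_params().
d_c: 0.3
d_m: 0.2
b: 5.0
mu: 0.1
tau: 1.0
N_f: 20
N_s: 10
n_steps: 200
seed: 1
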