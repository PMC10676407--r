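# Example configuration for rps-pulse / load_config(): a lattice run with a
# strong mid-length death pulse on species A.
engine: lattice
L: 100
p: 0.2
r: 0.4
d: 0.1
delta_d: 0.2
tau: 35
onset: 0
t_max: 500
seed: 42
n_runs: 1
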