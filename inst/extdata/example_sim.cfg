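# Example simulation configuration: excess-myosin stopped-flow mix at an
# intermediate calcium level (K_B = 0.47). Concentrations in uM, times in s.
actin_uM = 0.5
s1_uM = 5.0
duration_s = 0.3
K_B = 0.47
n_strands = 200
n_sites = 700
dt_s = 1e-5
burn_in_s = 0.5
record_every = 100
seed = 1
snapshot_times_s = 0.05,0.3
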