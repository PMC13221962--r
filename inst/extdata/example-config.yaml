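# Example study configuration for read_study_config().
# Omitted fields fall back to the protocol defaults.
D0: 22.5          # average cell diameter, um
mu: 0.3           # inactive-cell removal rate, 1/day
alpha: 0.015      # LQ radiosensitivity, 1/Gy
beta: 0.0015789   # LQ radiosensitivity, 1/Gy^2 (alpha / 9.5)
days_standard: [0, 2, 4, 6, 7]
days_rt: [0, 2, 4, 6, 7, 8, 9]
seed: 20260303
n_starts: 10
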