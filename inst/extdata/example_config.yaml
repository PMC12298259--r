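# Example run configuration for the synthetic QAMS pipeline.
# Contents are % dry weight; concentrations mg/mL; seed is mandatory.
seed: 2026
detectors:
  - PDA
  - ELSD
noise_rel: 0.02
n_replicates: 6
volume_ml: 5
mass_mg: 100
fx_provenance: intra_day
purity_correction: false
true_contents:
  G-Rb1: 1.46
  G-Rd: 0.96
  G-Rg1: 3.96
  M-R2: 5.51
  V-R2: 2.67
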