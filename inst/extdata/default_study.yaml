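agents:
- name: aflibercept
  molecular_weight: 115.0
  dose_mass: 1000.0
  injection_volume: 25.0
  kd_assay: 1.719e-13
  kd_temp_factor: 1.0
  binding_sites_per_drug: 1.0
  sites_per_vegf: 1.0
  ic50_nM: 2.42
  vitreal_half_life: 5.63
- name: brolucizumab
  molecular_weight: 26.0
  dose_mass: 3000.0
  injection_volume: 25.0
  kd_assay: 1.3e-12
  kd_temp_factor: 1.0
  binding_sites_per_drug: 1.0
  sites_per_vegf: 2.0
  ic50_nM: 5.74
  vitreal_half_life: 3.1
- name: ranibizumab
  molecular_weight: 48.0
  dose_mass: 250.0
  injection_volume: 25.0
  kd_assay: 2.18e-11
  kd_temp_factor: 1.0
  binding_sites_per_drug: 1.0
  sites_per_vegf: 2.0
  ic50_nM: 10.82
  vitreal_half_life: 3.15
geometry:
  vitreous_volume: 1.5
  aqueous_volume: 0.3
  aqueous_outflow: 3.0
  diffusion_path_length: 0.9
  temperature: 310.15
  vitreous_viscosity: 0.0007
design:
  vegf_dose_mass: 500.0
  vegf_injection_volume: 50.0
  vegf_molecular_weight: 38.2
  challenge_days:
  - 5.0
  - 26.0
  - 33.0
  - 40.0
  - 54.0
  - 68.0
  observation_lag: 47.0
  animals_per_group: 7.0
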