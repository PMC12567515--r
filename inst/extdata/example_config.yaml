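# Example run configuration: the default study conditions with a reduced
# history budget for a quick demonstration run. Any key omitted here is
# filled from the package defaults (see default_config()).
seed: 1
beam:
  energy_MeV: 2.0
  field: square
  side_um: 70
  flux_per_s: 2.0e+7
  duration_s: 10
  target_entrance_keV: 675
geometry:
  nucleus_radius_um: 5
  cell_radius_um: 12.5
  boron_sphere_radius_um: 1.5
  shell_count: 10
  shell_thickness_nm: 10
pbft:
  n_protons: 20000
  n_alphas: 5000
  batches: 5
bnct:
  fluence_cm2: 1.0e+12
  background_gamma_Gy: 0.05
  hydrogen_dose_Gy: 0.1
  ppm: [0, 1, 5, 10]
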