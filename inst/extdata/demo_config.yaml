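# Demo pipeline: binary LA/PA film at 20 A^2/molecule with mild demixing,
# chain-length staggering and partial LA desorption, followed by graph,
# structure and WHAM stages. Runs in well under five minutes on one CPU.
version: 1
seed: 7
output_dir: monomix_demo
protonation:
  ph_values: [2, 7, 8.2]
  composition: "LA:1,MA:2,PA:4,SA:3"
  totals: {LA: 20, MA: 40, PA: 80, SA: 60}
  policy: nearest
synth:
  n_molecules: 144
  mma: 20
  composition: "LA:0.5,PA:0.5"
  demix_J: 0.8
  demix_sweeps: 300
  stagger_offsets:
    - {species: LA, protonated: true, offset: 0.5}
    - {species: PA, protonated: true, offset: -0.5}
  desorb_fraction: 0.1
  desorb_species: LA
  n_frames: 5
  xy_jitter_sd: 0.3
  z_jitter_sd: 0.2
network:
  species: [LA, PA]
  cutoff: auto
  rdf_bin_width: 0.1
structure:
  deviation_bin_width: 0.25
  density_bin_width: 0.5
wham:
  potential: harmonic
  kappa: 2.0
  centers: [-3, 3, 0.5]
  k: 10
  n_steps: 4000
  dt: 0.005
  friction: 1
  grid: [-3.5, 3.5, 70]
  tol: 1.0e-6
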