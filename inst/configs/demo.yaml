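seed: 7
output_dir: monofilm_demo
tasks:
  - type: synth_isotherm
    name: dppc_like
    model: le-plateau-lc
    noise_sd: 0.05
    n_points: 250
  - type: analyze_isotherm
    input: dppc_like
  - type: synth_mixture
    name: chol_mix
    excess: xscaled
    excess_params:
      c: -2
    fractions: [0.25, 0.5, 0.75]
    pi_max: 40
  - type: mixing_gexc
    input: chol_mix
    pi_target: 35
  - type: synth_slab
    name: water_slab
    n_atoms: 500
    n_frames: 5
  - type: md_density
    input: water_slab
    reference: midplane
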