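# Human cell (osteoblast-like), homogenized single-compartment model.
#
# Young's modulus 4.5 kPa (AFM measurements on osteoblasts, ~1-10 kPa range);
# Poisson ratio 0.45 (near-incompressible, limited for linear elements).
# Conductivity 0.5 S/m: homogenized cytoplasm-dominated value used for
# tissue-scale DC models; higher than the dilute alginate gel, so the
# electric field inside the cell portion is lower than in the gel.
# Relative permittivity 70.
name: cell
elasticity:
  type: isotropic
  youngs_modulus: 4.5e+3
  poisson: 0.45
piezo_e: null
permittivity_rs: [70.0, 70.0, 70.0]
conductivity: 0.5
mu_r: 1.0
Ms: 0.0
lambda_s: 0.0
density: 1050.0
poling_axis: [0.0, 0.0, 1.0]
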