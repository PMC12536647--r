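# Cobalt ferrite (CoFe2O4) -- magnetostrictive core material.
#
# Elastic constants: cubic single-crystal values c11 = 286, c12 = 173,
#   c44 = 45.3 GPa (widely used in magnetoelectric composite modelling,
#   after Li/Bhagavantam compilations).
# lambda_s: -110 ppm, the standard measured polycrystalline value for
#   CoFe2O4 (single-crystal constants lambda_100 = -590 ppm,
#   lambda_111 = +120 ppm average higher, ~-164 ppm, but measured
#   polycrystal magnetostriction is the value used in composite modelling).
# mu_r and Ms: effective small-signal permeability 1.25 and nanoparticle-grade
#   saturation magnetization 5.5e4 A/m, consistent with the reported core
#   magnetization of a 45 nm particle at 300 mT (manufacturer data-sheet scale;
#   bulk CFO reaches ~4.25e5 A/m but nanoparticle values are far lower).
# Conductivity: semiconducting ferrite, negligible at these scales.
name: CFO
elasticity:
  type: voigt
  # GPa, Voigt order (11,22,33,23,13,12)
  matrix_gpa:
    - [286.0, 173.0, 173.0, 0.0, 0.0, 0.0]
    - [173.0, 286.0, 173.0, 0.0, 0.0, 0.0]
    - [173.0, 173.0, 286.0, 0.0, 0.0, 0.0]
    - [0.0, 0.0, 0.0, 45.3, 0.0, 0.0]
    - [0.0, 0.0, 0.0, 0.0, 45.3, 0.0]
    - [0.0, 0.0, 0.0, 0.0, 0.0, 45.3]
piezo_e: null
permittivity_rs: [10.0, 10.0, 10.0]
conductivity: 1.0e-5
mu_r: 1.25
Ms: 5.5e+4
lambda_s: -110.0e-6
density: 5300.0
poling_axis: [0.0, 0.0, 1.0]
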