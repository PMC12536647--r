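# Barium titanate (BaTiO3) -- piezoelectric shell material, poled along z.
#
# Poled-ceramic constants (Jaffe/Berlincourt compilation, the set shipped with
# commercial FEM material libraries for "barium titanate, poled"):
#   cE (GPa): c11 = 150.4, c12 = 65.6, c13 = 65.9, c33 = 145.5, c44 = 43.9,
#             c66 = (c11 - c12)/2.
#   e (C/m^2): e31 = -4.32, e33 = 17.36, e15 = 11.40.
#   Clamped relative permittivity: eps11 = 1115, eps33 = 1260.
# Not magnetostrictive: Ms = 0, lambda_s = 0.
name: BTO
elasticity:
  type: voigt
  matrix_gpa:
    - [150.4, 65.6, 65.9, 0.0, 0.0, 0.0]
    - [65.6, 150.4, 65.9, 0.0, 0.0, 0.0]
    - [65.9, 65.9, 145.5, 0.0, 0.0, 0.0]
    - [0.0, 0.0, 0.0, 43.9, 0.0, 0.0]
    - [0.0, 0.0, 0.0, 0.0, 43.9, 0.0]
    - [0.0, 0.0, 0.0, 0.0, 0.0, 42.4]
piezo_e:
  # C/m^2, rows E_x, E_y, E_z; columns Voigt (11,22,33,23,13,12)
  - [0.0, 0.0, 0.0, 0.0, 11.40, 0.0]
  - [0.0, 0.0, 0.0, 11.40, 0.0, 0.0]
  - [-4.32, -4.32, 17.36, 0.0, 0.0, 0.0]
permittivity_rs: [1115.0, 1115.0, 1260.0]
conductivity: 1.0e-9
mu_r: 1.0
Ms: 0.0
lambda_s: 0.0
density: 6020.0
poling_axis: [0.0, 0.0, 1.0]
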