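# Hydroxyapatite (Ca10(PO4)6(OH)2) -- piezoelectric bone-mineral particle,
# hexagonal, c-axis (strongest coefficient d33) along z.
#
# Elasticity: single-crystal hexagonal constants after Katz & Ukraincik:
#   c11 = 137, c12 = 42.5, c13 = 54.9, c33 = 172, c44 = 39.6 GPa,
#   c66 = (c11 - c12)/2.
# Piezoelectric coupling: strain-charge constants reported for HAP,
#   d33 = 2.0 pC/N, d31 = -0.5 pC/N, d15 = 1.0 pC/N, converted to the
#   stress-charge matrix e = d * cE:
#   e31 = d31*(c11 + c12) + d33*c13 = 0.0200 C/m^2
#   e33 = 2*d31*c13 + d33*c33     = 0.2891 C/m^2
#   e15 = d15*c44                  = 0.0396 C/m^2
# The c-axis coefficient dominates (|e33| >> |e31|), reproducing the reported
# d33 anisotropy of HAP.
# Relative permittivity ~10; electrically insulating.
name: HAP
elasticity:
  type: voigt
  matrix_gpa:
    - [137.0, 42.5, 54.9, 0.0, 0.0, 0.0]
    - [42.5, 137.0, 54.9, 0.0, 0.0, 0.0]
    - [54.9, 54.9, 172.0, 0.0, 0.0, 0.0]
    - [0.0, 0.0, 0.0, 39.6, 0.0, 0.0]
    - [0.0, 0.0, 0.0, 0.0, 39.6, 0.0]
    - [0.0, 0.0, 0.0, 0.0, 0.0, 47.25]
piezo_e:
  - [0.0, 0.0, 0.0, 0.0, 0.0396, 0.0]
  - [0.0, 0.0, 0.0, 0.0396, 0.0, 0.0]
  - [0.0200, 0.0200, 0.2891, 0.0, 0.0, 0.0]
permittivity_rs: [10.0, 10.0, 10.0]
conductivity: 1.0e-12
mu_r: 1.0
Ms: 0.0
lambda_s: 0.0
density: 3160.0
poling_axis: [0.0, 0.0, 1.0]
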