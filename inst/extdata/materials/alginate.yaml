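# Alginate hydrogel -- homogeneous isotropic, non-piezoelectric matrix.
#
# Young's modulus 30 kPa, representative of ionically crosslinked alginate
# used for cell encapsulation (literature range ~1-100 kPa). Poisson ratio
# 0.45: hydrogels are nearly incompressible; 0.45 is used to keep linear
# simplex elements free of volumetric locking.
# Conductivity 0.1 S/m (hydrated polysaccharide gel, below saline).
# Relative permittivity 80 (water-dominated).
name: alginate
elasticity:
  type: isotropic
  youngs_modulus: 30.0e+3
  poisson: 0.45
piezo_e: null
permittivity_rs: [80.0, 80.0, 80.0]
conductivity: 0.1
mu_r: 1.0
Ms: 0.0
lambda_s: 0.0
density: 1050.0
poling_axis: [0.0, 0.0, 1.0]
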