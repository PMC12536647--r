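# Default run configuration (schema version 1).
# Units: lengths um/nm as suffixed; fields tesla; potentials volts.
schema_version: 1
menp:
  B: 0.3
  core_radius: 45.0e-9
  shell_thickness: 25.0e-9
  gel_side: 1.0e-6
  h: 5.0e-9
# When null, stages (ii)-(iv) use the stage-(i) shell potential amplitude.
V0_override: null
concentration:
  spacings_um: [1.40, 1.00, 0.90, 0.80, 0.70, 0.65]
hap:
  lengths_nm: [100, 200, 400]
  rotations_deg: [0, 45, 90]
coupled3d:
  configs: [embedded, interface]
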