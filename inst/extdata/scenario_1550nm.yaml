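# Reference single-cell exposure: 1550 nm fs fibre laser, 50 MHz, 1.5 um
# spot, 24 mW average power, water medium, default membrane model.
exposure:
  wavelength: 1550 nm
  pulse_duration: 100 fs
  pulse_spacing: 20 ns
  average_power: 24 mW
  spot_diameter: 1.5 um
  exposure_time: 40 s
medium:
  density: 1000 kg/m^3
  specific_heat: 4200 J/(kg K)
  thermal_conductivity: 0.6 W/(m K)
  absorption_coefficient: 10 cm-1
membrane:
  cell_radius: 10 um
  membrane_thickness: 7 nm
  vm_threshold: 0.1 V
  thermo_factor: 100 K/V
  grad_threshold: 1e9 K/m
beam:
  waist_radius: 0.75 um
  wavelength: 1550 nm
synth:
  n_samples: 50   # 'n' alone is a YAML 1.1 boolean literal
  seed: 42
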