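# Default LITT simulation configuration. Any field may be omitted; library
# defaults (brain / blood / water / polycarbonate parameter sets) fill the
# gaps. Quantities are bare SI numbers or "value unit" strings.

laser:
  wavelength: 1064nm     # or 980nm (control parameter set)
  power: 15 W
  duration: 120 s

applicator:
  diffuser_length: 10 mm
  catheter_diameter: 1.55 mm
  coolant_wall_temperature: 25   # degC, isothermal inner wall

tissue_optical:          # defaults follow the wavelength
  absorption: 0.5 cm^-1
  scattering: 57 cm^-1
  anisotropy: 0.9

tissue_thermal:
  density: 1040 kg/m^3
  heat_capacity: 3590 J kg^-1 K^-1
  heat_conductivity: 0.503 W m^-1 K^-1

blood:
  density: 1050 kg/m^3
  heat_capacity: 3640 J kg^-1 K^-1
  perfusion_rate: 0.0048 1/s
  arterial_temperature: 37

damage:
  rate_constant: 3.1e98  # s^-1
  activation_energy: 6.28e5 J mol^-1
  gas_constant: 8.31
  threshold: 1

grid:
  spacing: 0.2 mm
  domain_radius: 40 mm
  domain_halflength: 40 mm

solver:
  optics: p1             # or mc
  dt: 0.25 s
  scheme: backward       # or crank-nicolson
  cooldown: 600 s        # post-laser damage accumulation window
  snapshot_interval: 2 s
  photons: 1.0e6         # mc backend only
  seed: 1
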