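# Summer preset: cooling pad open, setpoint 27.5 C
volume: 6375
floor_area: 1500
envelope_area: 920
solar_area: 1491
pos_fan_area: 6.7
duct_area: 45
pad_thickness: 0.15
radiation_coeff: 0.64
floor_htc: 6
envelope_htc: 0.93
air_density: 1.2
air_cp: 1006
flock_mass: 92900
egg_yield: 2700
n_birds: 48000
control:
  season: summer
  Tset: 27.5
  KP: 23
  KI: 15
  KD: 3
  pad_open: true
  L_min: 1858
  L_max: 7435
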