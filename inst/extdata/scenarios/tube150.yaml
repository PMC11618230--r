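name: tube150
geometry:
  type: tube
  diameter: 3.0e-04
  length: 3.0e-03
  target_h: 3.0e-05
  axial_stretch: 3.0
device:
  type: screen
  braid_angle: 150.0       # smaller pores than the 90 degree screen
  wire_diameter: 2.0e-05
  cell_side: 1.0e-04
  center_frac: 0.5
flow:
  type: velocity
  mean_velocity: 0.015
inlet:
  PT: 1.4
  AT: 2.41
  Fg: 7.0
coupling:
  total_time_target: 2.0
  max_coupled_steps: 500
  eps1: 1.0e-04
  eps2: 1.0e-03
transport:
  courant: 0.5
  scheme: upwind1
  fiber_length: 4.0e-05
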