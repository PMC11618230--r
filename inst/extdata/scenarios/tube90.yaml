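name: tube90
geometry:
  type: tube
  diameter: 3.0e-04        # 300 um
  length: 3.0e-03          # 3 mm
  target_h: 3.0e-05        # 30 um
  axial_stretch: 3.0
device:
  type: screen
  braid_angle: 90.0        # cell internal angle (deg)
  wire_diameter: 2.0e-05   # 20 um
  cell_side: 1.0e-04       # rhombic cell side (m)
  center_frac: 0.5         # screen position along the tube
flow:
  type: velocity
  mean_velocity: 0.015     # 1.5 cm/s
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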