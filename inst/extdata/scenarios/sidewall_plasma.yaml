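name: sidewall_plasma
geometry:
  type: sidewall
  vessel_d: 4.0e-03        # 4 mm parent vessel
  aneurysm_d: 8.0e-03      # 8 mm sac
  curvature_radius: 4.0e-02
  neck_d: 4.0e-03
  target_h: 4.5e-04
  vessel_length: 2.4e-02
device:
  type: helical
  n_wires: 48
  wire_diameter: 3.0e-05   # 30 um
  braid_angle: 90.0
  length: 1.6e-02
  # deployed against the vessel wall: radius = vessel_r - wire_r (computed
  # when absent)
flow:
  type: velocity
  flow_rate: 4.0e-06       # 4 cc/s
inlet:
  PT: 1.4
  AT: 2.41
  Fg: 7.0
coupling:
  total_time_target: 1.0
  max_coupled_steps: 500
  eps1: 1.0e-04
  eps2: 1.0e-03
transport:
  courant: 0.5
  scheme: upwind1
  fiber_length: 4.0e-05
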