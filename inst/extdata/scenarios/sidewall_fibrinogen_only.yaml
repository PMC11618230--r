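name: sidewall_fibrinogen_only
# Glass-model variant: clear fibrinogen concentrate, no thrombin pathway.
geometry:
  type: sidewall
  vessel_d: 4.0e-03
  aneurysm_d: 8.0e-03
  curvature_radius: 5.0e-02
  neck_d: 4.8e-03          # the glass model has a wider neck
  target_h: 4.5e-04
  vessel_length: 2.4e-02
device:
  type: helical
  n_wires: 48
  wire_diameter: 3.2e-05   # 32 um
  braid_angle: 90.0
  length: 2.0e-02          # 20 mm device
  nominal_diameter: 4.75e-03
flow:
  type: velocity
  flow_rate: 4.0e-06
inlet:
  PT: 0.0                  # fibrinogen concentrate: no (pro)thrombin
  AT: 0.0
  Fg_mg_dl: 330.0          # converted to uM (~9.7) at build time
reaction:
  Kwt: 0.0                 # thrombin pathway disabled
  Kth: 0.0
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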