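# Desk-scale 2D flapping-leaflet valve demonstration.
# Mesh: generate_2d_valve_channel(0.06, 0.02, 0.009, 0.0014, 0.0016,
#                                 n_leaflets = 2, leaflet_x = 0.018,
#                                 tilt_deg = 30)
# (the `run` subcommand builds this mesh when --mesh is not given).

materials:
  rho_fluid: 1060.0     # kg/m^3, blood
  rho_solid: 1000.0     # kg/m^3
  mu_f: 0.0027          # Pa s, blood viscosity
  mu_s: 8000.0          # Pa; soft demo leaflets (flex at channel scale)

cycle:
  T_cycle: 1.124        # s, one heart cycle
  T_systole: 0.4        # s, forward half-sine pulse
  T_reversal: 0.05      # s, backflow lobe completing closure
  U_peak: 0.32          # m/s
  U_reversal: 0.192     # m/s

solver:
  cfl_target: 0.5
  cfl_floor: 0.01
  kappa1: 1.0
  kappa2: 1.0
  picard_tol: 1.0e-6
  krylov: direct
  dt_max: 0.004
  t_end: 1.124

smoothing:
  pseudo_steps: 25
  quality_trigger: 5.0
  max_quality: 60.0

contact:
  enabled: true
  threshold: 0.0042     # m; just below the 4.4 mm resting tip gap
  method: geometric

output:
  save_every: 40
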