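# Default six-network poroelastic configuration.
# All quantities SI unless a value carries an explicit "mmHg" suffix.
# Every entry the reference literature does not pin down is listed here
# explicitly so that assumed defaults are always visible in run manifests.

elasticity:
  E_grey: 584.0            # Pa
  E_white: 1168.0          # Pa
  nu: 0.35                 # consistent with (lambda, G) = (505, 216) and (1010, 433)
  stiffness_perturbation_amplitude: 10.0   # Pa, white matter only
  perturbation_mode: iid   # iid | correlated
  perturbation_seed: 1

networks:
  alpha:       {a: 0.1,     c: 0.2,     e: 0.2,     v: 0.1,     l: 0.2,     g: 0.2}
  c_storage:   {a: 2.9e-4,  c: 2.9e-4,  e: 3.9e-4,  v: 1.5e-5,  l: 1.5e-5,  g: 1.5e-5}   # m^2/N
  k:           {a: 1.0e-10, c_grey: 1.0e-8, c_white: 1.0e-10, e: 1.0e-10, v: 1.0e-10, l: 2.0e-11, g: 5.0e-8}  # m^2
  mu:          {a: 3.5e-3,  c: 3.5e-3,  e: 8.9e-4,  v: 3.5e-3,  l: 8.9e-4,  g: 8.9e-4}   # Pa s (assumed: blood-like a/c/v, CSF-like e/l/g)
  phi: 0.3                 # total porosity (validity check only; assumed)
  Ke_tensor_mode: isotropic  # isotropic | field

transfer:
  omega:       {ac: 1.5e-19, cv: 1.5e-19, al: 2.8e-14, cl: 4.1e-9, vl: 4.1e-9, el: 4.1e-9, gl: 4.1e-9, eg: 4.1e-9}  # m^2 N^-1 s^-1
  valves:      # assumed default directions; every entry configurable
    ac: one_way_forward    # a -> c (forward blood flow)
    cv: one_way_forward    # c -> v
    al: one_way_forward    # periarterial influx a -> l
    cl: bidirectional
    vl: bidirectional
    el: bidirectional
    gl: bidirectional
    eg: bidirectional

boundary:
  p_ls: 13332.2            # Pa (= 100 mmHg, arterial-pressure-like glymphatic skull value)
  p_lv: 2445.0             # Pa
  p_gv: 1767.0             # Pa
  p_bp: 650.0              # Pa (venous, sagittal-sinus-like)
  Q_p: 5.8e-9              # m^3/s CSF production
  R: 8.5e+13               # outflow resistance constant (mu_e * R in Pa s m^-3)
  d: 3.0e-3                # m aqueduct diameter
  L: 70.0e-3               # m aqueduct length
  r_v: 0.02                # m ventricular reference radius

time:
  dt: 0.1                  # s
  period: 1.0              # s cardiac cycle
  n_cycles: 50
  convergence_tol: 1.0e-4  # cycle-to-cycle relative L2 tolerance

geometry:
  kind: shell              # shell | column | file
  dim: 2
  r_inner: 0.02            # m
  r_outer: 0.07            # m
  resolution: 8            # radial layers (angular count scales with it)
  grey_fraction: 0.5       # outer band fraction labelled GREY
  n_region_sectors: 5      # angular sectors standing in for atlas regions
  units: m                 # m | mm (file meshes only)

waveform:
  kind: synth              # synth | file
  mean_flow: 1.25e-5       # m^3/s (~750 ml/min, ICA+VA-like total)
  pulsatility: 0.4         # peak/mean - 1
  period: 1.0              # s
  n_samples: 101

solver:
  microcirculation_transit: true   # volumetric -Q_in (arterial) / +Q_out (venous) transit pair
  arterial_bc_mode: darcy_flux     # darcy_flux: Neumann datum makes Darcy influx integrate to the waveform
  aqueduct_inner_loop: false       # lag nonlocal couplings one step (O(dt) splitting)
  u1_mode: mean                    # mean | max ventricular normal displacement in the aqueduct relation
  transient_cycles_excluded: 2     # cycles excluded from convergence statistics

output:
  vtu_stride: 0            # write every Nth step as VTU (0 = none)
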