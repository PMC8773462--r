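# Delayed-activation scenario on the concentric-sphere cell model:
# membrane-bound synthesis (flux) from t_s = 10 s, cytosolic
# Michaelis-Menten degradation from t_d = 20 s.
name: delayed_start_sphere
geometry:
  type: sphere_shell
  R_o_um: 9.34
  R_i_um: 5.26
  edge_um: 2.4
  seed: 1
parameters:
  D_um2_per_s: 10
  E_AC_uM_per_s: 0
  V_max_uM_per_s: 0.295
  K_M_uM: 2
  C_o_uM: 0.05
  t_s_s: 10
  t_d_s: 20
  beta_uM_um_per_s:
    plasma_membrane: 2
integration:
  dt_s: 1
  t_end_s: 120
  snapshot_stride: 20
probes_um:
  - [9.34, 0, 0]
  - [7.8, 0, 0]
  - [5.26, 0, 0]
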