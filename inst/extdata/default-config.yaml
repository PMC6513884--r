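geometry:
  d_IPS: 3.0e-07
  d_EPS: 5.0e-07
  l_PS: 3.0e-07
  d_P: 1.0e-07
  l_P: 2.5e-05
  d_Syn: 2.7e-07
  l_Syn: 3.0e-07
  Vol_Syn: 8.5883e-16
  SA_PsECS_GECS: 1.5715e-14
constants:
  R: 8.31
  T: 310.0
  F: 96485.0
  k_B: 1.38e-23
  Q: 1.6022e-19
  eps0: 8.85e-12
  eps_r: 0.82
astrocyte:
  V_A: -0.0807
  V_m: -0.0807
  C_m: 0.01
  phi_w: 0.267
  g_Kir: 144.0
  g_K: 17.936399999999999
  g_Na: 0.9761
  g_ECS: 3.3
  g_ECS_Na: 111.375
  K_K: 0.018
  K_Na: 0.018
  K_Ca: 0.018
  PNKA_max: 1.0e-06
  K_Nai: 0.01
  K_KE: 0.0015
  I_bar_NCX: 1.0
  gamma: 0.5
  J0: 0.06
  tau_EAAT: 0.05
  glu_per_spike: 0.001
  z_K: 1.0
  z_Na: 1.0
  z_Ca: 2.0
  alpha_EAAT: 0.0032
  beta_EAAT: 28.800000000000001
  r_g: 5.0e-07
  s_g: 9.0e-06
  K_PsC0: 0.1
  Na_PsC0: 0.015
  Ca_PsC0: 1.0e-07
  K_PsECS0: 0.004
  Na_PsECS0: 0.135
  Ca_PsECS: 0.0015
  K_GECS: 0.004
  Na_GECS: 0.135
  Ca_GECS: 0.0015
  K_AS: 0.1
  Na_AS: 0.015
  Ca_AS: 1.0e-07
  Glu_ECS: 2.5e-08
  Glu_PsC: 0.0015
  H_PsC: 5.999999999999999e-08
  H_PsECS: 4.0e-08
neuron:
  C_m: 0.01
  g_NaNeu: 1200.0
  g_KNeu: 360.0
  g_LNeu: 3.0
  g_KBNeu: 1.0522
  g_NaBNeu: 2.3217
  E_NaNeu: 0.115
  E_KNeu: -0.012
  E_LNeu: 0.010613
  PNKA_maxNeu: 3.7863e-08
  K_NaiNeu: 0.01
  K_KENeu: 0.0015
  Na_Syn: 0.015
  K_Syn: 0.1
  spike_threshold: 0.05
  refractory: 0.002
options:
  include_h_gate: yes
  k_background_in_psc: yes
  kir_sqrt: no
  nernst_valence: no
  pf_valence_charge: no
  conc_floor: 1.0e-12
protocol:
  dt: 1.0e-05
  t_settle: 6.0
  t_stim: 60.0
  t_post: 60.0
  record_stride: 100.0
  seed: 1
  stimulus:
    type: pulse
    rate: 10.0
    amplitude: .na.real
    pulse_width: 0.002
    spike_times: []
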