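{
  "lattice_side": 50,
  "S_im": 40,
  "k0": 1.2,
  "tau_pit_range": [1, 2],
  "tau_endo_mean": 4,
  "tau_endo_sd": 1,
  "a": 0.2,
  "b": 0.02,
  "C": 1.1,
  "K": 20,
  "tau_rab5_unit": "min",
  "d_EE": 0.05,
  "d_s": 0.05,
  "k_exo": 1,
  "tau_bud_range": [1.5, 2.5],
  "tau_exo_mean": 2,
  "tau_exo_sd": 0.5,
  "h_mean": 0.4,
  "h_sd": 0.02,
  "tau_s": 0.38,
  "dt": 0.1,
  "lattice_spacing": 0.2,
  "n_surface_init": 150,
  "n_ee_init": 100,
  "t_start": -10,
  "t_end": 50,
  "ep_t_peaks": [5, 8.5, 12, 15.5, 19],
  "ep_tau_decay": 4,
  "ep_target_integral": 25500,
  "epm_fraction": 0.25
}
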