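{
  "seed": 1,
  "hh": {
    "C_m": 1, "g_Q": 2, "g_K": 8, "g_L": 0.5,
    "E_Q": -160, "E_K": -100, "E_L": -80,
    "tau_act_Q": 0.3, "tau_act_K": 1.5,
    "tau_inact_Q": 2, "tau_deact_K": 0.5, "tau_rec_Q": 8,
    "I_half_Q": 2, "k_I_Q": 1,
    "V_window_lo": -130, "V_window_hi": -95, "k_window": 4,
    "V_half_K": -120, "k_K": 4,
    "S_on_K": 4.7, "k_on_K": 0.5, "S_off_K": 11.2, "k_off_K": 0.8,
    "q_plat": 0.97, "k_plat": 0.4,
    "alpha_ROS": 0.1, "delta_ROS": 0.1,
    "irradiance": 15.99, "irradiance_threshold": 15.99,
    "p_K": 1, "V_T": 26
  },
  "fdf": {
    "D": 5, "k_decay": 6, "k_matrix": 0.55, "k_uptake": 0,
    "c_thresh": 1, "sigma_release": 27,
    "t_fire": 0.1, "t_refract": 18, "tht_decay": 1.5, "c_bright": 3,
    "repol_rate": 0, "core_source": 40, "core_delay": 1.5,
    "habituation_delay": 10, "tht_plateau": 0.9,
    "grid_dx": 1.5, "dt": 0.04, "frame_dt": 0.2,
    "domain_factor": 3, "max_agents": 20000, "seed": 1
  }
}
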