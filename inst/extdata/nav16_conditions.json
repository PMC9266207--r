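{
  "WT": {
    "density_scale": 1.0,
    "Coff": 0.5, "Oon": 0.75, "Ooff": 0.005, "epsilon": 0,
    "alpha0": 150, "beta0": 3, "alpha_i0": 150, "beta_i0": 3, "gamma0": 150,
    "delta0": 40, "zeta0": 0.03, "Con": 0.005,
    "k_alpha": 20, "k_beta": 20, "k_zeta": 25
  },
  "WT+CN21": {
    "density_scale": 0.300,
    "Coff": 0.5, "Oon": 1.3, "Ooff": 0.005, "epsilon": 0,
    "alpha0": 92, "beta0": 3, "alpha_i0": 150, "beta_i0": 3, "gamma0": 150,
    "delta0": 40, "zeta0": 0.03, "Con": 0.005,
    "k_alpha": 20, "k_beta": 20, "k_zeta": 25
  },
  "R639C": {
    "density_scale": 1.72,
    "Coff": 0.25, "Oon": 0.75, "Ooff": 0.007, "epsilon": 0,
    "alpha0": 277.5, "beta0": 3.7, "alpha_i0": 110, "beta_i0": 4, "gamma0": 130,
    "delta0": 40, "zeta0": 0.03, "Con": 0.005,
    "k_alpha": 20, "k_beta": 20, "k_zeta": 25
  },
  "R639C+CN21": {
    "density_scale": 0.878,
    "Coff": 0.25, "Oon": 0.75, "Ooff": 0.007, "epsilon": 0,
    "alpha0": 277.5, "beta0": 3.7, "alpha_i0": 110, "beta_i0": 4, "gamma0": 130,
    "delta0": 40, "zeta0": 0.03, "Con": 0.005,
    "k_alpha": 20, "k_beta": 20, "k_zeta": 25
  },
  "R850Q": {
    "density_scale": 1.23,
    "Coff": 0.4, "Oon": 1.018, "Ooff": 0.018, "epsilon": 0,
    "alpha0": 85, "beta0": 0.9, "alpha_i0": 126, "beta_i0": 3.4, "gamma0": 137,
    "delta0": 40, "zeta0": 0.03, "Con": 0.005,
    "k_alpha": 20, "k_beta": 20, "k_zeta": 25
  },
  "R850Q+CN21": {
    "density_scale": 0.835,
    "Coff": 0.4, "Oon": 1.018, "Ooff": 0.018, "epsilon": 0,
    "alpha0": 50.3, "beta0": 0.9, "alpha_i0": 250, "beta_i0": 4, "gamma0": 137,
    "delta0": 40, "zeta0": 0.03, "Con": 0.005,
    "k_alpha": 20, "k_beta": 20, "k_zeta": 25
  }
}
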