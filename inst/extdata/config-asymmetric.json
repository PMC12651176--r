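{
  "grid": { "n": 32, "L": 6.283185307179586 },
  "model": {
    "tau": 1.0,
    "activation": { "beta": 2.0, "u_star": 0.5 },
    "kernel": { "family": "shifted_gaussian", "amplitude": 1.0, "width": 0.5,
                "shift": 0.7853981633974483, "normalization": 1.0 },
    "fixed_point": { "selector": "largest" }
  },
  "noise": { "family": "white", "T": 1.0 },
  "simulate": { "dt": 0.002, "n_steps": 300000, "burn_in": 5000,
                "seed": 13, "initial": "stationary", "save_stride": 1 },
  "tasks": ["epr-analytic", "spectrum", "simulate", "epr-path",
            "check-equilibrium"],
  "output": { "dir": "amari-epr-asymmetric" }
}
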