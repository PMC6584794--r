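{
  "tpm": {
    "b": [9.513425, 1.312385, -0.448513, -0.581447, 1.775869, 0.007221],
    "std_error": [1.332116, 0.594033, 0.05174, 0.101911, 0.149039, 0.000775]
  },
  "nic": {
    "beta": [0.009809, -0.000005],
    "std_error": [0.001369, 0.000055]
  },
  "meta": {
    "device": "NJOY pen-style e-cigarette, top-coil tank, no adjustable settings",
    "e_liquid": "AVAIL Tobacco Row, labeled 1.8% nicotine (0.0140 mg/mg measured un-puffed), 50:50 PG/VG",
    "response_units": {"tpm": "ln(mg/mL)", "nic": "mg/mg"},
    "regressors": ["1", "ln(q)", "d", "ln(q)^2", "ln(d/1000)", "q*d"],
    "fit": {"n_obs": 204, "n_conditions": 34, "r_squared": 0.905,
            "adj_r_squared": 0.903, "rmse": 0.012,
            "nic_r_squared": 0.0002, "nic_rmse": 0.0025},
    "envelope": {"q": [10, 100], "d": [1, 5]},
    "note": "Device-and-liquid-specific reference coefficients; not transferable to other products.",
    "checksum": 11588744
  }
}
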