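{
  "comment": "Reported downstream rates (s^-1) for each fitted model variant, and the ground-truth parameter set of the synthetic western-blot data generator. Receptor (k_a, k_i) and feedback (k_aut, k_du) truth values are generator choices (the study's corresponding estimates are not published); they are set so that the low-dose (0.029 nM IL-1) half-maximum delay of IKKp exceeds 10 min, the high-dose response is fast, and the latent low-dose amplitude stays clearly below the high-dose amplitude within 120 min.",
  "downstream_rates": {
    "original":               {"k_p": 0.095, "k_dp": 7.6e-4, "k_uv": 2.4e-4},
    "traf":                   {"k_p": 0.095, "k_dp": 9.3e-4, "k_uv": 2.6e-4},
    "double_phos":            {"k_p": 0.095, "k_dp": 7.5e-4, "k_uv": 2.3e-4},
    "irreversible_inhibitor": {"k_p": 0.095, "k_dp": 7.2e-4, "k_uv": 2.3e-4}
  },
  "synthetic_ground_truth": {
    "variant": "traf",
    "parameters": {
      "k_a": 0.002, "k_i": 0.002,
      "k_p": 0.095, "k_dp": 9.3e-4, "k_uv": 2.6e-4,
      "k_aut": 1.0e-3, "k_du": 4.0e-3
    },
    "observation": {"scale_high": 1, "scale_low": 2, "dose_threshold": 0.1}
  }
}
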