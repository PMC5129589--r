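[
  {
    "couplingId": "3JHNHA",
    "c2": 7.09,
    "c1": -1.42,
    "c0": 1.55,
    "delta": -60,
    "source": "Original",
    "comment": "backbone 3J(HN,Ha) vs phi; standard literature coefficients, theta = phi - 60"
  },
  {
    "couplingId": "3JHNHA",
    "c2": 7.90,
    "c1": -1.05,
    "c0": 0.65,
    "delta": -60,
    "source": "Schmidt",
    "comment": "backbone 3J(HN,Ha) vs phi; self-consistent cross-validated coefficients"
  }
]
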