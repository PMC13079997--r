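69d0b7a7a92a00f31b62d4c6aeb647e9908af49455e1906c5dbaf4d8da35dbeb  score2_coefficients.json
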