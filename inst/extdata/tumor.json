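{"mu": 0.446, "mu1": 116.0, "eta": 20}
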