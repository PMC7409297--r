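{"eps": 0.004, "dS": 0.030, "dM": 0.104, "m2": 338}
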