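{"A1": 0, "A2": 0, "A3": 0.51, "A4": 0.54, "t_start": 5}
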