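{"p0": 0.479, "p1": 0.133, "nu0": 0.087, "nu1": 5.591, "d0": 0.05, "m": 1000}
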