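{"xi": 0.002, "lean_fraction": 0.40, "muscle_share": 0.95, "stem_share": 0.05}
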