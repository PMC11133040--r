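1, 4, 9, 16, 25, 36, 49, 64, 81, 100, 121, 144
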