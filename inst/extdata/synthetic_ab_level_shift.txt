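phase	score
A	161.4
A	162.9
A	157.5
A	160.6
A	161.8
A	161.7
A	162.4
A	160.5
A	159.5
B	169.9
B	169.1
B	169.2
B	169.9
B	173.6
B	178.5
B	173.3
B	169.9
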