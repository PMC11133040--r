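phase	score
A	153.4
A	148.2
A	149
A	149.4
A	148.5
A	148.6
B	151.1
B	149.8
B	160.2
B	163.3
B	160.5
B	164.1
B	163.4
B	160.5
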