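phase	hours
G1	11
S	8
G2	4
M	1
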