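species	copy_number
RI	6
BH	5
BT	5
CA	3
PC	4
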