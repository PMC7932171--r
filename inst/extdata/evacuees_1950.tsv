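region	total_population	n_evacuees	printed_proportion
SOF	667500	70686	0.11
SWF	631000	57834	0.09
TAV	553300	68187	0.12
OST	607200	32487	0.05
NOS+KAI	359800	12495	0.03
LAP	167100	6069	0.04
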