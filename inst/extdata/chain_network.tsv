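id	substrates	products	lb	ub	exchange
R1		A	0	1000	TRUE
R2	A	B	0	1000	FALSE
R3	B		0	1000	TRUE
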