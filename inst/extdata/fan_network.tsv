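id	substrates	products	lb	ub	exchange
R1		B	0	1000	TRUE
R2	2 B		0	1000	TRUE
R3	2 B	A	0	1000	FALSE
R4	2 A		0	1000	TRUE
R5	2 B	C	0	1000	FALSE
R6	2 C		0	1000	TRUE
R7	B		0	1000	TRUE
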