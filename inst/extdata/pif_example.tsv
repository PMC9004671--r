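receptor	res5x50	res3x40	res6x44
CB1	L	V	L
ADRB2	P	I	F
EXAMPLE_PVF	P	V	F
EXAMPLE_PIL	P	I	L
EXAMPLE_GAP	-	I	F
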