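segment	chain	start	end
TM1	A	113	142
TM2	A	150	179
TM3	A	186	215
TM4	A	222	251
TM5	A	275	304
TM6	A	335	364
TM7	A	372	401
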