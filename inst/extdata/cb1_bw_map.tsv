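label	chain	resseq
1.36	A	120
2.61	A	174
3.25	A	189
3.36	A	200
3.40	A	204
3.50	A	214
5.50	A	286
5.58	A	294
6.34	A	342
6.44	A	352
6.48	A	356
7.36	A	380
7.53	A	397
N-term	A	102
ECL2	A	268
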