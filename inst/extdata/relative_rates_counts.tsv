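gene	codon_position	invariable	mX	mY	mO	chi2_printed	p_printed
evm.chr2.642	1	515	4	14	100	5.56	0.018
evm.chr2.642	2	574	6	6	49	0.00	1.00
evm.chr2.642	3	408	17	23	179	0.90	0.34
evm.chr2.643	1	100	0	2	54	2.00	0.16
evm.chr2.643	2	100	1	2	25	0.33	0.56
evm.chr2.643	3	79	2	1	34	0.33	0.56
evm.chr2.644	1	317	2	2	86	0.00	1.00
evm.chr2.644	2	261	3	6	55	0.14	0.71
evm.chr2.644	3	298	0	2	56	2.00	0.16
evm.chr2.645	1	198	1	0	45	1.00	0.32
evm.chr2.645	2	208	1	1	64	0.00	1.00
evm.chr2.645	3	170	0	0	584	0.00	1.00
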