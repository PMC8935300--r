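gene	cds_length	syn_dif	syn_pos	ks_printed	nsyn_dif	nsyn_pos	ka_printed	ka_ks_printed
evm.chr2.642	1932	43.50	455.25	0.102	44.50	1476.75	0.031	0.30
evm.chr2.643	331	3.00	80.33	0.038	5.00	249.67	0.020	0.53
evm.chr2.644	1230	9.00	275.75	0.033	8.00	954.25	0.008	0.25
evm.chr2.645	2760	11.00	622.75	0.018	14.00	2137.25	0.007	0.37
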