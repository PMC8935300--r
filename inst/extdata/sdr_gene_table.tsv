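gene_id	pos_mb	tested	y_snps
evm.chr2.630	218.69	TRUE	0
evm.chr2.631	218.91	FALSE	NA
evm.chr2.632	219.10	FALSE	NA
evm.chr2.633	219.24	FALSE	NA
evm.chr2.634	219.66	FALSE	NA
evm.chr2.635	220.06	FALSE	NA
evm.chr2.636	220.18	TRUE	0
evm.chr2.637	220.69	TRUE	0
evm.chr2.638	220.99	TRUE	0
evm.chr2.639	221.46	FALSE	NA
evm.chr2.640	221.71	FALSE	NA
evm.chr2.641	222.14	FALSE	NA
evm.chr2.642	222.55	TRUE	32
evm.chr2.643	222.97	TRUE	5
evm.chr2.644	223.53	TRUE	11
evm.chr2.645	223.87	TRUE	13
evm.chr2.646	224.37	FALSE	NA
evm.chr2.647	224.49	FALSE	NA
evm.chr2.648	224.88	FALSE	NA
evm.chr2.649	225.22	TRUE	0
evm.chr2.650	225.42	TRUE	0
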