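gene	log2fc	direction	lfdr
mmGene0003	-1.51056	-1	2.23047e-84
mmGene0018	-1.38186	-1	9.89994e-66
mmGene0020	1.53412	1	2.23047e-84
mmGene0041	-1.56628	-1	6.43848e-89
mmGene0045	1.51036	1	2.23047e-84
mmGene0053	1.54073	1	1.7023e-87
mmGene0058	1.40751	1	3.13111e-70
mmGene0067	1.53929	1	9.92103e-87
mmGene0070	-1.51006	-1	3.42476e-79
mmGene0084	-1.57759	-1	2.69224e-90
mmGene0085	1.59225	1	1.35587e-91
mmGene0099	1.46703	1	3.42476e-79
mmGene0103	1.55432	1	1.7023e-87
mmGene0104	1.46438	1	7.20989e-73
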