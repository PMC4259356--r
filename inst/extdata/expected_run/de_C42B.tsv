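gene	log2fc	direction	lfdr
mmGene0003	-1.50337	-1	7.30543e-74
mmGene0018	-1.4503	-1	9.61092e-67
mmGene0020	1.41638	1	4.66871e-66
mmGene0041	-1.51388	-1	2.69819e-74
mmGene0045	1.54134	1	2.29239e-78
mmGene0053	 1.6245	1	2.27967e-78
mmGene0058	1.42562	1	1.52607e-66
mmGene0067	1.49792	1	7.1896e-73
mmGene0070	-1.5396	-1	2.65935e-75
mmGene0084	-1.42124	-1	4.62262e-66
mmGene0085	1.48875	1	4.40076e-69
mmGene0099	1.54407	1	2.27967e-78
mmGene0103	1.64805	1	9.45511e-87
mmGene0104	1.41403	1	2.16957e-60
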