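probe_id	match_len	identity	flagged	partner
mmGene0001_p02	22	0.9200	TRUE	hsTX0059
mmGene0001_p03	25	1.0000	TRUE	hsTX0033
mmGene0003_p02	20	0.8400	TRUE	hsTX0081
mmGene0003_p06	16	0.7200	TRUE	hsTX0145
mmGene0005_p02	15	0.6400	TRUE	hsTX0034
mmGene0010_p04	21	0.8400	TRUE	hsTX0013
mmGene0010_p06	20	0.8000	TRUE	hsTX0091
mmGene0010_p09	15	0.7200	TRUE	hsTX0058
mmGene0012_p08	22	0.9200	TRUE	hsTX0128
mmGene0014_p08	19	0.7600	TRUE	hsTX0034
mmGene0015_p03	21	0.8400	TRUE	hsTX0030
mmGene0016_p04	23	0.9600	TRUE	hsTX0015
mmGene0023_p05	24	0.9600	TRUE	hsTX0065
mmGene0024_p02	15	0.8000	TRUE	hsTX0104
mmGene0024_p11	25	1.0000	TRUE	hsTX0021
mmGene0026_p03	18	0.8400	TRUE	hsTX0025
mmGene0028_p09	22	0.9200	TRUE	hsTX0018
mmGene0029_p01	21	0.8800	TRUE	hsTX0087
mmGene0032_p03	21	0.9200	TRUE	hsTX0090
mmGene0033_p05	21	0.9200	TRUE	hsTX0125
mmGene0034_p03	25	1.0000	TRUE	hsTX0069
mmGene0035_p11	15	0.7200	TRUE	hsTX0067
mmGene0036_p08	19	0.8800	TRUE	hsTX0130
mmGene0041_p01	19	0.8000	TRUE	hsTX0065
mmGene0043_p09	25	1.0000	TRUE	hsTX0091
mmGene0043_p11	21	0.8800	TRUE	hsTX0142
mmGene0046_p05	17	0.7600	TRUE	hsTX0085
mmGene0047_p11	20	0.8000	TRUE	hsTX0015
mmGene0050_p04	23	0.9200	TRUE	hsTX0091
mmGene0051_p04	21	0.8800	TRUE	hsTX0114
mmGene0052_p08	17	0.7600	TRUE	hsTX0069
mmGene0055_p11	25	1.0000	TRUE	hsTX0051
mmGene0058_p06	18	0.7200	TRUE	hsTX0143
mmGene0058_p11	15	0.6800	TRUE	hsTX0128
mmGene0060_p01	20	0.8000	TRUE	hsTX0123
mmGene0063_p10	24	0.9600	TRUE	hsTX0057
mmGene0067_p05	19	0.8800	TRUE	hsTX0084
mmGene0072_p01	16	0.7200	TRUE	hsTX0075
mmGene0072_p05	15	0.7200	TRUE	hsTX0132
mmGene0072_p07	20	0.8400	TRUE	hsTX0008
mmGene0075_p05	20	0.8000	TRUE	hsTX0144
mmGene0075_p09	25	1.0000	TRUE	hsTX0005
mmGene0077_p01	25	1.0000	TRUE	hsTX0025
mmGene0079_p10	20	0.8400	TRUE	hsTX0093
mmGene0081_p03	21	0.8800	TRUE	hsTX0024
mmGene0081_p08	25	1.0000	TRUE	hsTX0013
mmGene0085_p08	17	0.7600	TRUE	hsTX0146
mmGene0087_p07	22	0.9200	TRUE	hsTX0092
mmGene0092_p10	25	1.0000	TRUE	hsTX0058
mmGene0094_p03	20	0.8400	TRUE	hsTX0145
mmGene0096_p05	17	0.7600	TRUE	hsTX0147
mmGene0097_p06	25	1.0000	TRUE	hsTX0110
mmGene0098_p03	19	0.8800	TRUE	hsTX0081
mmGene0108_p09	20	0.8400	TRUE	hsTX0005
mmGene0111_p11	24	0.9600	TRUE	hsTX0133
mmGene0112_p10	20	0.8800	TRUE	hsTX0144
mmGene0114_p07	21	0.8400	TRUE	hsTX0113
mmGene0117_p05	23	0.9200	TRUE	hsTX0127
mmGene0117_p10	18	0.7600	TRUE	hsTX0114
mmGene0122_p08	21	0.8800	TRUE	hsTX0115
mmGene0122_p10	15	0.7200	TRUE	hsTX0125
mmGene0123_p03	15	0.6400	TRUE	hsTX0015
mmGene0123_p06	22	0.9200	TRUE	hsTX0101
mmGene0126_p01	17	0.6000	TRUE	hsTX0102
mmGene0130_p06	19	0.7600	TRUE	hsTX0089
mmGene0131_p05	23	0.9200	TRUE	hsTX0114
mmGene0131_p06	19	0.8400	TRUE	hsTX0084
mmGene0131_p10	20	0.8000	TRUE	hsTX0028
mmGene0133_p10	22	0.8800	TRUE	hsTX0129
mmGene0134_p01	20	0.8000	TRUE	hsTX0104
mmGene0135_p08	16	0.6800	TRUE	hsTX0068
mmGene0138_p05	16	0.7200	TRUE	hsTX0010
mmGene0139_p03	19	0.9200	TRUE	hsTX0083
mmGene0139_p05	23	0.9200	TRUE	hsTX0025
mmGene0140_p02	21	0.8400	TRUE	hsTX0026
mmGene0143_p10	25	1.0000	TRUE	hsTX0118
mmGene0145_p08	22	0.9200	TRUE	hsTX0050
mmGene0146_p01	24	0.9600	TRUE	hsTX0014
mmGene0147_p05	23	0.9200	TRUE	hsTX0112
mmGene0147_p06	25	1.0000	TRUE	hsTX0150
mmGene0149_p02	19	0.8400	TRUE	hsTX0017
mmGene0149_p11	18	0.8400	TRUE	hsTX0036
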