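signature	k	K	n	N	coverage_pct	fold	p
hsc_niche_like	6	6	14	150	    100	10.7143	2.10044e-07
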