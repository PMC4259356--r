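stage	category	n_removed	n_remaining
1	inflammatory	1	13
2	non-osteotropic	1	12
3	osteotropic	1	11
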