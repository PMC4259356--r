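region	count
A&B	3
A&B&core	11
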