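metric	value
common	14
uniqueA	0
uniqueB	0
discordant	0
r2	0.99719
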