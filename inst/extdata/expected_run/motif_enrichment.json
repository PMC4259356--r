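{"motif":"synthTF","EF":1.89994,"p":0.0584708,"freq_cluster":0.545455,"freq_background":0.287091,"n_resamples":2000,"reported":false}
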