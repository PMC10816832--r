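strategy	statistic	ogms
current	count	6150
doubled	median	4370
tripled	median	3993
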