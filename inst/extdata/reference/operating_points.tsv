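system	procedure	bucket	threshold
UKN1	sps	1x	1
UKN1	sps	20x	1000
UKK2	sps	1x	270
UKK2	sps	20x	360
mean	sps	1x	130
mean	sps	20x	500
UKN1	top1000	1x	0.2
UKN1	top1000	20x	0.4
UKK2	top1000	1x	0.25
UKK2	top1000	20x	0.15
mean	top1000	1x	0.36
mean	top1000	20x	0.29
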