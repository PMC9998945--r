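taxon	GH13	GH5	GT2	CE1	PL1	CBM48	AA3
Fibrobacter succinogenes	12	8	5	3	2	4	0
Treponema bryantii	6	2	7	1	0	2	1
Ruminococcus flavefaciens	9	11	4	5	3	6	0
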