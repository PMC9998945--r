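name	taxonomy_id	taxonomy_lvl	kraken_assigned_reads	added_reads	new_est_reads	fraction_total_reads
Fibrobacter succinogenes	59374	S	10250	830	11080	0.554
Treponema bryantii	163262	S	5210	410	5620	0.281
Ruminococcus flavefaciens	1265	S	3050	250	3300	0.165
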