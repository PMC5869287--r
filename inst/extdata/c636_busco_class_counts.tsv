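bin	genes_found	genes_separated	genes_collapsed	genes_only_separated	genes_only_collapsed	inst_separated	inst_collapsed	inst_other
1	825	704	113	704	113	704	113	8
2	1668	1662	57	1600	2	3262	59	15
3	98	98	9	80	0	275	10	9
4	24	24	1	23	0	94	2	0
5-8	9	9	0	9	0	57	0	0
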