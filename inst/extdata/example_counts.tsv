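#lib_total_a=1000000
#lib_total_b=1200000
gene_id	length	count_a	count_b
geneA	1000	120	480
geneB	2500	300	310
geneC	800	0	45
geneD	1500	60	0
geneE	3000	900	1100
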