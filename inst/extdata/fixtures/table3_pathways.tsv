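pathway	n_genes	ancient_genes_with_pvs	ancient_gene_pct	ancient_pvs	modern_genes_with_pvs	modern_gene_pct	modern_pvs	notes
FA	49	27	55	615	30	61	926	
HR	37	21	57	636	21	57	916	text says HR PVs in 21 (67.7%) of 37 genes; table prints 21 (57)
MMR	22	8	36	225	8	36	188	
NER	42	13	31	95	13	31	163	
NHEJ	13	6	46	64	7	54	129	
DDR_response	15	3	20	82	5	33	86	
BER	32	7	22	46	7	22	72	
DR	34	12	35	36	11	32	36	
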