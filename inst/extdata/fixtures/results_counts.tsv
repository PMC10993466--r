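key	value
clinvar_pvs	20272
clinvar_genes_with_pvs	91
ddr_panel_genes	169
snv_pvs	7432
snv_genes	87
shared_pvs	1497
sharing_species	97
total_species	100
primate_shared_entries	53
ancient_samples	5031
ancient_pvs	1266
ancient_carriers	1019
ancient_genes	73
dated_carriers	959
carriers_within_5000	717
carriers_5000_10000	214
carriers_before_10000	28
recurrent_pvs	67
recurrent_genes	33
modern_pvs	1781
founder_pvs	68
founder_genes	7
brca1_founder_pvs	44
neanderthal_pvs	5
positive_selection_genes	12
neutral_selection_genes	4
negative_selection_genes	57
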