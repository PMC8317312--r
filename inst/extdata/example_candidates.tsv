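name	chrom	start	end	copy_number	n_snps	printed_length	case_cn0	case_cn1	case_cn3	case_cn4	control_cn0	control_cn1	control_cn3	control_cn4
AFG1L_SNX3	chr6	108570894	108694389	3	15	123496	0	0	0	0	0	0	0	0
VWDE	chr7	12371801	12439672	3	35	67872	0	0	0	0	0	0	1	0
ZNF804A	chr2	185421477	185564834	3	24	143358	0	0	0	0	0	0	0	0
CNTN6_CNTN4	chr3	1154559	2400967	3	605	1246409	0	7	4	0	0	7	13	0
OR_CLUSTER_ABCA1	chr9	107311368	107699196	1	246	387829	0	0	1	0	0	0	0	0
TUBGCP5_CYFIP1_NIPA1	chr15	22750305	23226254	3	113	475950	0	9	13	0	0	16	28	0
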