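key	value
utr5_sites	2300
cds_sites	18133
utr3_sites	4220
total_sites	24653
total_transcripts	8603
cds_a_to_g	2769
cds_g_to_a	2854
cds_c_to_u	2909
cds_u_to_c	2974
cds_four_type_total	11506
endo_genes	7036
endo_edited	1922
endo_edited_pct	27.3
other_edited_pct	19.5
go_cul4_k	75
go_cul4_size	132
go_cul4_pct	56.8
go_exocyst_k	19
go_exocyst_size	30
go_exocyst_pct	63.3
est_covered	2171
est_confirmed	1157
est_confirmed_pct	53.3
cluster_edited_total	546
cluster_ppr_total	46
chloroplast_total_sites	20
chloroplast_codon2_count	18
chloroplast_c_to_u_count	19
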