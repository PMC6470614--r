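# Published amino-acid composition (% of residues) of the Palmaria sp.
# (Japan) plastid proteome, per functional category, with wet-lab proximate
# reference values for P. palmata (ref_total_aa = % of total AA,
# ref_protein = % of protein). Literature values, not computed here.
# Cysteine is printed under its oxidised dimer name "Cystine".
aa	plastid	genetic_system	ribosomal_proteins	photosystems	atp_synthesis	metabolism	transport	unknown	ref_total_aa	ref_protein
Alanine	6.4	5.6	6.8	7.6	8.7	6.4	5.8	4.5	7.5	6.7
Arginine	4.6	5.1	6.8	4.1	3.8	4.0	3.6	4.1	6.2	5.1
Aspartic acid	4.5	5.6	4.1	4.0	4.6	5.4	3.9	3.8	9.3	18.5
Asparagine	5.5	5.9	5.2	4.8	4.2	5.6	5.6	6.4	NA	NA
Cystine	1.1	0.8	0.7	1.0	0.2	1.4	1.2	1.5	1.3	0
Glutamic acid	5.7	6.4	6.2	4.6	7.2	6.0	6.2	4.7	13	9.9
Glutamine	4.2	4.5	4.1	3.8	5.5	4.3	3.9	4.3	NA	NA
Glycine	6.3	5.7	7.0	7.6	7.1	6.6	5.4	3.7	7.2	13.3
Histidine	1.9	1.9	1.9	1.9	0.7	2.3	1.4	2.1	2.1	0.5
Isoleucine	9.0	10.0	8.7	7.5	9.3	9.0	11.1	10.0	5.3	3.7
Leucine	10.6	10.1	8.7	10.4	12.0	10.4	12.2	12.9	7.8	7.1
Lysine	6.5	7.3	9.3	4.4	5.5	5.8	5.3	7.0	8.2	3.3
Methionine	2.2	1.8	2.1	2.6	2.0	2.4	1.9	1.8	1.9	2.7
Phenylalanine	4.1	3.2	2.7	5.8	3.4	3.5	4.8	5.1	5.2	5.1
Proline	3.7	3.6	3.6	4.1	3.7	3.9	3.1	3.4	4.4	NA
Serine	7.4	7.0	6.3	7.8	6.8	7.2	7.8	8.6	4.6	6.3
Threonine	5.6	5.2	5.8	5.6	5.9	5.6	6.0	5.3	4.5	3.6
Tryptophan	1.0	0.5	0.5	1.9	0.4	0.8	0.9	1.3	NA	NA
Tyrosine	3.6	3.5	2.6	3.9	2.4	3.4	4.2	4.7	4.5	3.4
Valine	6.3	6.6	7.0	6.6	6.9	6.2	5.9	4.9	7.3	6.9
Total_AA	50333	7010	8981	11017	1975	11213	3184	6953	NA	NA
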