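# Published ACE-inhibitory tripeptide counts for the P. palmata plastid
# proteome (comparator species): literature values, not computed here.
class	database	plastid	genetic_system	ribosomal_proteins	photosystems	atp_synthesis	metabolism	transport	unknown
XXP	34	263	47	39	63	10	63	20	21
XXY	20	133	23	13	29	7	28	12	21
XXA	6	68	8	13	20	6	13	3	5
XXL	5	79	6	10	25	2	20	5	11
XXW	5	4	0	0	3	0	1	0	0
XXG	3	51	6	16	8	0	16	2	3
XXR	3	27	2	10	3	0	7	0	5
XXV	3	33	5	8	9	1	7	2	1
XXF	2	6	0	0	3	0	2	0	1
XXK	2	37	9	11	3	4	7	1	2
XXN	2	5	0	1	1	0	2	0	1
XXX	4	36	7	8	6	0	9	5	1
Total	89	742	113	129	173	30	175	50	72
Total_AA	NA	50229	7009	8981	11013	1970	11237	3188	6831
Peptide_AA_pct	NA	1.48	1.61	1.44	1.57	1.52	1.56	1.57	1.05
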