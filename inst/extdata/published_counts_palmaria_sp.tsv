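# Published ACE-inhibitory tripeptide counts for the Palmaria sp. (Japan)
# plastid proteome: literature values, not computed by this package.
# database = tripeptides per C-terminal class in the IC50 < 20 uM screen;
# remaining columns = matches per functional category. The printed grand
# total (751) differs from the sum of the class rows (753); both are kept
# as published.
class	database	plastid	genetic_system	ribosomal_proteins	photosystems	atp_synthesis	metabolism	transport	unknown
XXP	34	260	48	38	62	10	61	20	21
XXY	20	140	21	13	30	7	31	13	25
XXA	6	66	9	11	21	5	13	3	4
XXL	5	78	5	11	27	2	19	5	9
XXW	5	4	0	0	3	0	1	0	0
XXG	3	51	5	16	8	0	16	2	4
XXR	3	31	4	10	3	0	7	0	7
XXV	3	33	5	8	10	1	6	2	1
XXF	2	7	0	0	3	0	2	0	2
XXK	2	39	8	12	3	3	8	1	4
XXN	2	5	0	1	1	0	2	0	1
XXX	4	39	8	8	6	0	10	5	2
Total	89	751	113	128	177	28	176	51	80
Total_AA	NA	50333	7010	8981	11017	1975	11213	3184	6953
Peptide_AA_pct	NA	1.49	1.61	1.43	1.61	1.42	1.57	1.60	1.15
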