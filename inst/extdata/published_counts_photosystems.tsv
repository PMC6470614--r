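# Published ACE-inhibitory tripeptide counts within the photosystem
# subcategories of the Palmaria sp. (Japan) plastid: literature values.
class	phycobilisomes	photosystem_I	photosystem_II	cytochrome_complex	redox_system
XXP	11	21	17	7	6
XXY	9	8	7	3	3
XXA	6	4	8	1	2
XXL	6	12	4	5	0
XXW	0	3	0	0	0
XXG	3	1	4	0	0
XXR	1	1	1	0	0
XXV	3	2	3	2	0
XXF	0	0	2	1	0
XXK	0	1	2	0	0
XXN	0	0	0	0	1
XXX	3	0	3	0	0
Total	42	53	51	19	12
Total_AA	2644	2654	2582	1784	1353
Peptide_AA_pct	1.59	2.00	1.98	1.07	0.89
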