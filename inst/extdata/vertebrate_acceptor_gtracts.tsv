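gene_symbol	species	clade	transcript_id	exon_rank	exon_size	sequence
CAMK1	human	other_mammals	ENST00000256460	9	79	gtcttgggggtttag
CAMK1	marsupial_panel	marsupials	NA	NA	NA	1
CAMK1	bird_panel	birds	NA	NA	NA	0
CAMK1	reptile_panel	reptiles	NA	NA	NA	0
CAMK1	fish_panel	fish	NA	NA	NA	0
CNOT3	human	other_mammals	ENST00000358389	3	276	gttctgtgggggcag
CNOT3	marsupial_panel	marsupials	NA	NA	NA	1
CNOT3	bird_panel	birds	NA	NA	NA	0
CNOT3	reptile_panel	reptiles	NA	NA	NA	0
CNOT3	fish_panel	fish	NA	NA	NA	0
DUSP12	human	other_mammals	ENST00000367943	5	187	gtttgggggttgcag
DUSP12	marsupial_panel	marsupials	NA	NA	NA	1
DUSP12	bird_panel	birds	NA	NA	NA	0
DUSP12	reptile_panel	reptiles	NA	NA	NA	0
DUSP12	fish_panel	fish	NA	NA	NA	0
FES	human	other_mammals	ENST00000328850	6	138	ccgtctcgggggcag
FES	marsupial_panel	marsupials	NA	NA	NA	1
FES	bird_panel	birds	NA	NA	NA	0
FES	reptile_panel	reptiles	NA	NA	NA	0
FES	fish_panel	fish	NA	NA	NA	0
TRPV1	human	other_mammals	ENST00000174621	7	180	gctccccgggggcag
TRPV1	marsupial_panel	marsupials	NA	NA	NA	0
TRPV1	bird_panel	birds	NA	NA	NA	0
TRPV1	reptile_panel	reptiles	NA	NA	NA	0
TRPV1	fish_panel	fish	NA	NA	NA	0
SLC44A2	human	other_mammals	ENST00000380614	22	104	ccggggggagcccag
SLC44A2	marsupial_panel	marsupials	NA	NA	NA	1
SLC44A2	bird_panel	birds	NA	NA	NA	0
SLC44A2	reptile_panel	reptiles	NA	NA	NA	0
SLC44A2	fish_panel	fish	NA	NA	NA	0
RQCD1	human	other_mammals	ENST00000273064	7	92	ttttgggggaaacag
RQCD1	marsupial_panel	marsupials	NA	NA	NA	1
RQCD1	bird_panel	birds	NA	NA	NA	0
RQCD1	reptile_panel	reptiles	NA	NA	NA	0
RQCD1	fish_panel	fish	NA	NA	NA	0
PFN2	human	other_mammals	ENST00000239940	2	193	tttggtggggggcag
PFN2	marsupial_panel	marsupials	NA	NA	NA	0
PFN2	bird_panel	birds	NA	NA	NA	0
PFN2	reptile_panel	reptiles	NA	NA	NA	0
PFN2	fish_panel	fish	NA	NA	NA	0
PDZK1	human	other_mammals	ENST00000339729	6	197	gttgggggagggtag
PDZK1	marsupial_panel	marsupials	NA	NA	NA	1
PDZK1	bird_panel	birds	NA	NA	NA	0
PDZK1	reptile_panel	reptiles	NA	NA	NA	0
PDZK1	fish_panel	fish	NA	NA	NA	0
LRRC23	human	other_mammals	ENST00000007969	6	137	gccctgggggtctag
LRRC23	marsupial_panel	marsupials	NA	NA	NA	0
LRRC23	bird_panel	birds	NA	NA	NA	0
LRRC23	reptile_panel	reptiles	NA	NA	NA	0
LRRC23	fish_panel	fish	NA	NA	NA	0
LAMB1	human	other_mammals	ENST00000222399	22	225	tttatcgggtgacag
LAMB1	marsupial_panel	marsupials	NA	NA	NA	0
LAMB1	bird_panel	birds	NA	NA	NA	0
LAMB1	reptile_panel	reptiles	NA	NA	NA	0
LAMB1	fish_panel	fish	NA	NA	NA	0
C3orf62	human	other_mammals	ENST00000343010	2	92	acctgggggctgcag
C3orf62	marsupial_panel	marsupials	NA	NA	NA	1
C3orf62	bird_panel	birds	NA	NA	NA	0
C3orf62	reptile_panel	reptiles	NA	NA	NA	0
C3orf62	fish_panel	fish	NA	NA	NA	0
PRMT5	human	other_mammals	ENST00000324366	3	86	ggtgggggagtgcag
PRMT5	marsupial_panel	marsupials	NA	NA	NA	1
PRMT5	bird_panel	birds	NA	NA	NA	0
PRMT5	reptile_panel	reptiles	NA	NA	NA	0
PRMT5	fish_panel	fish	NA	NA	NA	0
PAOX	human	other_mammals	ENST00000368534	2	159	tgtttgcgggggaag
PAOX	marsupial_panel	marsupials	NA	NA	NA	1
PAOX	bird_panel	birds	NA	NA	NA	1
PAOX	reptile_panel	reptiles	NA	NA	NA	1
PAOX	fish_panel	fish	NA	NA	NA	1
METTL13	human	other_mammals	ENST00000367736	2	176	cctgggcgggggcag
METTL13	marsupial_panel	marsupials	NA	NA	NA	1
METTL13	bird_panel	birds	NA	NA	NA	1
METTL13	reptile_panel	reptiles	NA	NA	NA	1
METTL13	fish_panel	fish	NA	NA	NA	1
MICA	human	other_mammals	ENST00000364810	4	288	gctgggtgggggcag
MICA	marsupial_panel	marsupials	NA	NA	NA	1
MICA	bird_panel	birds	NA	NA	NA	0
MICA	reptile_panel	reptiles	NA	NA	NA	ND
MICA	fish_panel	fish	NA	NA	NA	ND
FAM113	human	other_mammals	ENST00000309144	4	239	ggggggggtgggtag
FAM113	marsupial_panel	marsupials	NA	NA	NA	1
FAM113	bird_panel	birds	NA	NA	NA	ND
FAM113	reptile_panel	reptiles	NA	NA	NA	0
FAM113	fish_panel	fish	NA	NA	NA	0
PAX8	human	other_mammals	ENST00000263334	5	176	cccggggggtaccag
PAX8	marsupial_panel	marsupials	NA	NA	NA	1
PAX8	bird_panel	birds	NA	NA	NA	ND
PAX8	reptile_panel	reptiles	NA	NA	NA	0
PAX8	fish_panel	fish	NA	NA	NA	0
ABCC11	human	other_mammals	ENST00000356608	2	117	ttctgggaaacgaag
ABCC11	marsupial_panel	marsupials	NA	NA	NA	0
ABCC11	bird_panel	birds	NA	NA	NA	ND
ABCC11	reptile_panel	reptiles	NA	NA	NA	0
ABCC11	fish_panel	fish	NA	NA	NA	0
HLA-G	human	other_mammals	ENST00000383504	3	276	aaggggtggggccag
HLA-G	marsupial_panel	marsupials	NA	NA	NA	1
HLA-G	bird_panel	birds	NA	NA	NA	ND
HLA-G	reptile_panel	reptiles	NA	NA	NA	ND
HLA-G	fish_panel	fish	NA	NA	NA	ND
HLA-H	human	other_mammals	ENST00000360432	3	276	cgggggcggggccag
HLA-H	marsupial_panel	marsupials	NA	NA	NA	1
HLA-H	bird_panel	birds	NA	NA	NA	ND
HLA-H	reptile_panel	reptiles	NA	NA	NA	ND
HLA-H	fish_panel	fish	NA	NA	NA	ND
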