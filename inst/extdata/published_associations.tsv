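protein	trait_id	trait_name	r_discovery	r_replication	p_discovery	p_replication	n_discovery	n_replication
IgG	PGP69	M9 in total neutral plasma glycans (GPn)	-0.69	-0.36	8.0e-50	1.5e-2	344	46
IgG	PGP93	core fucosylated structures	0.68	0.31	3.7e-47	3.7e-2	344	46
IgG	PGP65	A2G2 in total neutral plasma glycans (GPn)	-0.51	-0.35	3.8e-24	1.6e-2	344	46
IgG	PGP75	fucosylation of digalactosylated structures in total neutral plasma glycans	0.44	0.35	1.3e-17	1.9e-2	344	46
IgG	PGP14	A2G2S(6)1 + A2G2S(3)1	-0.44	-0.30	1.4e-17	4.3e-2	344	46
IgM	PGP16	FA2BG2S(3)1 + FA2BG2S(6)1	0.59	0.61	3.6e-34	6.0e-6	344	46
IgM	PGP44	monosialylation of core-fucosylated digalactosylated structures with bisecting GlcNAc	0.51	0.48	2.5e-24	8.0e-4	344	46
IgM	PGP11	FA2BG2	0.48	0.32	1.3e-21	2.9e-2	344	46
IgM	PGP42	monosialylation of core-fucosylated digalactosylated structures without bisecting GlcNAc	0.46	0.41	4.6e-19	4.1e-3	344	46
IgM	PGP48	ratio of fucosylated monosialylated and disialylated structures (with bisecting GlcNAc)	0.45	0.38	1.7e-18	8.3e-3	344	46
IgM	PGP54	ratio of fucosylated monosialylated structures with and without bisecting GlcNAc	0.40	0.56	1.1e-14	4.4e-5	344	46
IgM	PGP55	the incidence of bisecting GlcNAc in all fucosylated monosialylated structures	0.40	0.56	1.1e-14	4.4e-5	344	46
SERPIND1	PGP97	trisialylated structures	0.53	0.29	8.0e-27	4.9e-2	344	46
SERPIND1	PGP102	trigalactosylated structures	0.53	0.35	8.7e-26	1.7e-2	344	46
SERPIND1	PGP105	triantennary structures	0.52	0.34	7.0e-25	2.0e-2	344	46
FUT5	PGP24	A3G3S(3,3,3)3	0.53	0.39	3.6e-26	7.9e-3	344	46
FUT5	PGP30	A4G4S(3,3,3)3	0.51	0.50	3.8e-24	3.8e-4	344	46
FUT5	PGP32	A4F1G3S(3,3,3)3 + A4F1G3S(3,3,6)3 + A4F1G3S(3,6,6)3	0.51	0.43	4.4e-24	3.1e-3	344	46
FUT5	PGP106	tetraantennary structures	0.48	0.46	1.9e-21	1.4e-3	344	46
FUT5	PGP110	ratio of trisialylated and tetrasialylated tetragalactosylated structures	0.47	0.48	9.4e-21	8.3e-4	344	46
FUT5	PGP103	tetragalactosylated structures	0.47	0.45	2.4e-20	1.5e-3	344	46
FUT5	PGP36	A4F1G4S(3,3,3,6)4	0.45	0.30	6.3e-19	4.0e-2	344	46
FUT5	PGP92	antennary fucosylated structures	0.40	0.37	6.6e-15	1.1e-2	344	46
CD5L	PGP16	FA2BG2S(3)1 + FA2BG2S(6)1	0.51	0.40	6.3e-24	5.7e-3	344	46
CD5L	PGP108	glycan structures with bisecting GlcNAc	0.40	0.41	6.7e-15	4.9e-3	344	46
CRP	PGP97	trisialylated structures	0.45	0.38	3.3e-18	8.8e-3	344	46
CRP	PGP29	A3F1G3S(3,3,3)3 + A3F1G3S(3,3,6)3	0.44	0.39	7.1e-18	7.1e-3	344	46
F9 (IX)	PGP29	A3F1G3S(3,3,3)3 + A3F1G3S(3,3,6)3	0.44	0.38	6.9e-18	9.7e-3	344	46
F9 (IXab)	PGP29	A3F1G3S(3,3,3)3 + A3F1G3S(3,3,6)3	0.44	0.38	7.1e-18	9.3e-3	344	46
F9 (IX)	PGP92	antennary fucosylated structures	0.41	0.31	4.5e-15	3.5e-2	344	46
FCGR3B	PGP3	A2(6)BG1	0.44	0.30	1.3e-17	4.2e-2	344	46
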