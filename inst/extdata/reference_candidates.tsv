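ensembl_id	gene_symbol	betweenness	permutation_fdr	interaction_score	interaction_partner	alignment_score	alignment_partner
ENSP00000364133	TGFBR1	217	0.006	999	TGFB3	682	ACVR1B
ENSP00000380280	FGFR1	437	0	999	FGF8	239	KIT
ENSP00000351905	TGFBR2	1	0.028	999	TGFB3	231	ACVR1B
ENSP00000241416	ACVR2A	266	0	998	INHBA	233	ACVR1C
ENSP00000266058	SLIT1	212	0	997	ROBO2	1995	SLIT2
ENSP00000266646	INHBE	199	0	997	ACVR1B	149	INHBA
ENSP00000309913	TBX5	2	0.034	996	GATA4	244	TBX3
ENSP00000263640	ACVR1	136	0.002	994	AMH	439	ACVR1C
ENSP00000250448	FOXA1	5	0.034	993	SHH	120	FOXF2
ENSP00000245451	BMP4	172	0.012	993	SHH	105	NODAL
ENSP00000168712	FGF4	107	0.004	992	SHH	104	FGF9
ENSP00000254227	NR0B2	232	0.018	989	NR5A1	129	NR0B1
ENSP00000363708	BMPR2	127	0.004	981	GDF9	194	ACVR1B
ENSP00000364709	F10	107	0.008	980	SERPINA10	116	CORIN
ENSP00000277541	NOTCH1	394	0.002	975	SHH	385	JAG2
ENSP00000379204	BMP7	366	0	974	SHH	105	TGFB2
ENSP00000295731	IHH	114	0.002	969	TGFB2	436	SHH
ENSP00000256646	NOTCH2	107	0	966	JAG2	376	JAG2
ENSP00000264568	BMPR1B	2	0.016	944	SOX9	451	ACVR1C
ENSP00000366534	FOXH1	120	0.014	913	FOXF2	103	FOXF2
ENSP00000355192	CACNA1S	107	0.018	907	CACNA1H	226	CACNA1H
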