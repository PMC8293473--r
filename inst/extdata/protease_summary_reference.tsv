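protease_gene	protease_name	cleaved_proteins	n_down	n_up	fold_change	avg_fibrosis	avg_nofibrosis	p_value
CTSD	Cathepsin D	HBA1 (5)	5	0	0.03	752.59	23977.22	0.0006
MMP12	Macrophage metalloelastase	COL2A1 (1)	1	0	0.32	43.02	135.00	0.0002
MMP8	Neutrophil collagenase	COL2A1 (1)	1	0	0.32	43.02	135.00	0.0002
MMP2	72 kDa type IV collagenase	COL1A1 (1), COL1A2 (2)	1	2	1.26	126.59	100.10	0.1580
MMP13	Collagenase 3	COL2A1 (1), COL18A1 (2), COL1A2 (2)	1	4	1.40	314.37	224.63	0.0002
CTSB	Cathepsin B	COL18A1 (1)	0	1	1.41	611.67	433.29	0.0006
CTSK	Cathepsin K	COL18A1 (1)	0	1	1.41	611.67	433.29	0.0006
CTSL	Procathepsin L	COL18A1 (1)	0	1	1.41	611.67	433.29	0.0006
MMP20	Matrix metalloproteinase-20	COL18A1 (1)	0	1	1.41	611.67	433.29	0.0006
MMP7	Matrilysin	COL18A1 (1)	0	1	1.41	611.67	433.29	0.0006
MMP14	Matrix metalloproteinase-14	COL18A1 (1), COL1A2 (2)	0	3	1.65	305.72	184.95	0.0001
MMP1	Interstitial collagenase	COL2A1 (1)	0	1	2.23	412.14	184.53	0.0006
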