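peptide_id	gene_symbol	sequence	uniprot_id	mass_da	migration_time_min	start_pos	stop_pos	adj_p_bh	mean_fibrosis	mean_nofibrosis	fold_change
FPP01	COL10A1	GHPGPSGPPGKpGYGSpGLQGEpGLPGPPGPS	Q03692	NA	NA	NA	NA	2.42e-4	782.77	380.77	2.056
FPP02	COL1A2	GPQGVQGGKGEQGPPGPPGFQGLPGPSGpAGEVGKpGERG	P08123	NA	NA	NA	NA	2.42e-4	1151.22	272.13	4.230
FPP03	COL1A2	DQGPVGRTGEVGAVGpPGFAGEKGPSGEAGTAGPpGTpGP	P08123	NA	NA	NA	NA	8.56e-4	196.08	75.14	2.610
FPP04	AHSG	SLGSPSGEVSHPRKT	P02765	NA	NA	NA	NA	8.72e-4	2282.82	975.54	2.340
FPP05	AHSG	VVSLGSPSGEVSHPRKT	P02765	NA	NA	NA	NA	9.37e-3	11404.37	7829.98	1.457
FPP06	PIGR	LFAEEKAVADTRDQADGSRASVDSGSSEEQGGSSRA	P01833	NA	NA	NA	NA	1.22e-2	774.23	654.63	1.183
FPP07	COL1A2	VGRTGEVGAVGPpGFAGEKGPSGEAGTAGPpGTpGP	P08123	NA	NA	NA	NA	1.82e-2	109.41	46.41	2.357
FPP08	COL3A1	ARGLpGppGSNGNPGPPGPSGSPGKDGPPGPAGNTGAPG	P02461	NA	NA	NA	NA	2.34e-2	902.6	594.85	1.517
FPP09	SERPINC1	FSPEKSKLPGIVAEGRDDLYVSDAFHKAF	P01008	NA	NA	NA	NA	2.34e-2	9438.98	5838.02	1.617
FPP10	COL2A1	GETGAAGpPGpAGPAGERGEQGAPGP	P02458	NA	NA	NA	NA	2.34e-2	43.02	135	0.319
FPP11	COL4A1	pGIPGFPGSKGEMGVMGTPGQPGSPGPVGAPGLPGEKGDH	P02462	NA	NA	NA	NA	2.34e-2	3045.2	1456.47	2.091
FPP12	COL1A1	ANGApGNDGAKGDAGApGApGSQGApGLQGMpGERGAAGLPGp	P02452	NA	NA	NA	NA	2.69e-2	1210.38	814.9	1.485
FPP13	COL3A1	ApGPAGSRGApGPQGpRGDKGETGERG	P02461	NA	NA	NA	NA	2.69e-2	1103.52	618.43	1.784
FPP14	COL1A1	GADGQPGAKGEpGDAGAKGDAGPpGPAGP	P02452	NA	NA	NA	NA	2.69e-2	108.1	388.09	0.279
FPP15	COL1A1	ANGApGNDGAKGDAGApGApGSQGApGLQGMpGERGAAGLpGp	P02452	NA	NA	NA	NA	2.74e-2	447.16	170.81	2.618
FPP16	HBA1	AAHLPAEFTPAVHASLDKFL	P69905	NA	NA	NA	NA	2.81e-2	610.19	14067.56	0.043
FPP17	COL1A1	ADGQpGAKGEpGDAGAKGDAGPPGPAGP	P02452	NA	NA	NA	NA	2.81e-2	212.86	365.65	0.582
FPP18	COL3A1	EGGKGAAGpPGPpGAAGTpGLQG	P02461	NA	NA	NA	NA	2.81e-2	689.84	500.7	1.378
FPP19	COL22A1	GTEGKKGEAGPPGLPGPpGIAGpQGSQGERGADGEVGQKGDQGHPGVPGFMGPPGNPGP	Q8NFW1	NA	NA	NA	NA	2.81e-2	192.19	159.22	1.207
FPP20	AHSG	GVVSLGSPSGEVSHPRKT	P02765	NA	NA	NA	NA	2.81e-2	2476.64	1429.55	1.732
FPP21	PIGR	FAEEKAVADTRDQADGSRASVDSGSSEEQGGSSRALVSTLVPL	P01833	NA	NA	NA	NA	3.06e-2	891.67	377.71	2.361
FPP22	COL2A1	ppGSNGNpGPPGPPGPSGKDGPKGARGDSGPPGRAGEPG	P02458	NA	NA	NA	NA	3.50e-2	412.14	184.53	2.233
FPP23	COL18A1	DDILASPPRLPEPQPYPGAPHHSS	P39060	NA	NA	NA	NA	3.77e-2	611.67	433.29	1.412
FPP24	COL3A1	EpGRDGVpGGPGm	P02461	NA	NA	NA	NA	3.77e-2	2254.17	1608.12	1.402
FPP25	HBA1	AAHLPAEFTPAVHASLDKFLAS	P69905	NA	NA	NA	NA	4.15e-2	847.52	30583.66	0.028
FPP26	FGA	DEAGSEADHEGTHSTKRGHAKSRPV	P02671	NA	NA	NA	NA	4.15e-2	31926.35	22421.31	1.424
FPP27	AHSG	VSLGSPSGEVSHPRKT	P02765	NA	NA	NA	NA	4.15e-2	3680.2	2187.3	1.683
FPP28	COL3A1	GpGSDGKPGPpG	P02461	NA	NA	NA	NA	4.86e-2	145.26	347.21	0.418
FPP29	COL1A1	GSpGSpGPDGKTGPPGPAG	P02452	NA	NA	NA	NA	4.86e-2	74.29	178.76	0.416
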