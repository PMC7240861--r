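pathway	set_id	input_number	background_number	p_value	corrected_p	genes
Neuronal system	R-HSA-112316	8	339	0.004	0.048	ABCC8;PPFIA1;LRFN4;TSPOAP1;BEGAIN;GAD2;SYT10;KCNV2
Neurotransmitter release cycle	R-HSA-112310	3	50	0.007	0.064	TSPOAP1;PPFIA1;GAD2
Acetylcholine neurotransmitter release cycle	R-HSA-264642	2	16	0.008	0.068	TSPOAP1;PPFIA1
Serotonin neurotransmitter release cycle	R-HSA-181429	2	17	0.008	0.072	TSPOAP1;PPFIA1
Norepinephrine neurotransmitter release cycle	R-HSA-181430	2	17	0.008	0.072	TSPOAP1;PPFIA1
Dopamine neurotransmitter release cycle	R-HSA-212676	2	22	0.013	0.096	TSPOAP1;PPFIA1
Glutamate neurotransmitter release cycle	R-HSA-210500	2	23	0.014	0.100	TSPOAP1;PPFIA1
Axon guidance	R-HSA-422475	9	549	0.023	0.133	EPHB4;LAMC1;MMP2;DOK4;CSF2RB;SCN1A;EVL;ROBO1;PIK3CB
Cation-coupled chloride cotransporters	R-HSA-426117	1	7	0.057	0.197	SLC12A4
Interactions of neurexins and neuroligins at synapses	R-HSA-6794361	2	57	0.070	0.212	BEGAIN;SYT10
Protein-protein interactions at synapses	R-HSA-6794362	2	57	0.070	0.212	BEGAIN;SYT10
SLAM protein interactions at the synapses	R-HSA-8849932	1	21	0.149	0.284	LRFN4
Potassium channels	R-HSA-1296071	2	99	0.169	0.300	ABCC8;KCNV2
Metal ion SLC transporters	R-HSA-425410	1	25	0.174	0.304	HEPH
Transmission across chemical synapses	R-HSA-112315	3	208	0.201	0.329	TSPOAP1;PPFIA1;GAD2
Inwardly rectifying K+ channels	R-HSA-1296065	1	31	0.209	0.334	ABCC8
Vesicle-mediated transport	R-HSA-5653656	6	573	0.251	0.369	AP1G2;CD163;CFTR;PRKAG2;HIP1R;COG4
Voltage gated potassium channels	R-HSA-1296072	1	43	0.276	0.389	KCNV2
Cardiac conduction	R-HSA-5576891	2	141	0.281	0.393	SCN1A;NOS1
Ion homeostasis	R-HSA-5578775	1	56	0.342	0.439	NOS1
Ca2+ pathway	R-HSA-4086398	1	61	0.366	0.456	TCF7L1
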