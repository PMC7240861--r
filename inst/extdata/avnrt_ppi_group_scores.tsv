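gene	n_nodes_1	total_score_1	mean_score_1	n_nodes_2	total_score_2	mean_score_2	combined_total	combined_nodes
RYR2	37	23.226	0.628	10	6.533	0.653	14.880	23.5
NOS1	12	9.121	0.760	5	4.469	0.894	6.795	8.5
SCN1A	18	10.844	0.602	3	1.297	0.432	6.071	10.5
CFTR	8	5.596	0.700	5	3.750	0.75	4.673	6.5
EPHB4	4	2.463	0.616	11	6.508	0.592	4.483	7.5
PRKAG2	14	7.370	0.526	2	1.299	0.650	4.335	8
ROBO1	3	1.958	0.653	10	6.524	0.652	4.241	6.5
ASPH	4	3.105	0.776	3	2.897	0.966	3.001	3.5
MMP2	4	2.741	0.685	4	2.589	0.647	2.665	4
ABCC8	8	4.278	0.535	1	0.496	0.496	2.387	4.5
ATP2C2	4	2.077	0.519	5	2.687	0.537	2.382	4.5
COL5A1	3	2.28	0.760	3	2.280	0.760	2.280	3
CSF2RB	2	1.819	0.910	3	2.340	0.780	2.080	2.5
PIK3CB	3	1.977	0.659	2	1.361	0.681	1.669	2.5
COL4A3	3	1.782	0.594	2	1.356	0.678	1.569	2.5
HIPK2	3	2.433	0.811	1	0.625	0.625	1.529	2
SFTPA2	2	1.841	0.921	1	0.917	0.917	1.379	1.5
HIP1R	2	1.800	0.900	1	0.900	0.900	1.350	1.5
EVL	1	0.925	0.925	2	1.503	0.752	1.214	1.5
SLC26A4	2	1.143	0.572	2	1.186	0.593	1.165	2
PPFIA1	1	0.933	0.933	1	0.933	0.933	0.933	1
GAD2	2	0.929	0.465	2	0.929	0.465	0.929	2
PSMB11	1	0.905	0.905	1	0.905	0.905	0.905	1
TCF7L1	1	0.625	0.625	1	0.625	0.625	0.625	1
LAMC1	1	0.553	0.553	1	0.553	0.553	0.553	1
KCNV2	1	0.926	0.926	NA	NA	NA	0.463	0.5
COG4	1	0.902	0.902	NA	NA	NA	0.451	0.5
SLC12A4	1	0.591	0.591	NA	NA	NA	0.296	0.5
SYT10	1	0.400	0.400	NA	NA	NA	0.200	0.5
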