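gene	carrier_cases_maf01	carrier_controls_maf01	carrier_cases_maf001	carrier_controls_maf001
CFTR	68	51	6	4
EVL	12	0	12	0
HIP1R	7	0	2	0
ABCC8	6	0	3	0
COG4	7	1	3	0
LAMC1	7	1	1	1
AP1G2	7	1	1	0
GAD2	5	0	1	0
CSF2RB	5	0	2	0
BEGAIN	5	0	3	0
SYT10	5	0	1	0
LRFN4	5	0	5	0
NOS1	42	35	39	32
SLC12A4	8	2	5	2
ROBO1	8	2	7	1
SFTPA2	12	5	11	3
TSPOAP1	9	3	4	3
KCNV2	6	1	2	1
PIK3CB	6	1	2	1
CD163	4	0	4	0
PRKAG2	4	0	1	0
DOK4	4	0	2	0
HEPH	4	0	2	0
SCN1A	4	0	3	0
PPFIA1	4	0	3	0
EPHB4	7	2	6	1
MMP2	7	2	4	1
TCF3	7	2	3	1
COL5A1	8	3	7	2
ATP2C2	8	4	6	1
SLC26A4	6	3	4	0
ASPH	6	3	4	0
PSMB11	7	4	4	0
RYR2	10	8	8	3
COL4A3	6	4	5	0
HIPK2	7	9	5	0
SLC9B1	82	100	77	84
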