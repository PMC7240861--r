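gene	n_rare_variants_maf001
KCNJ12	11
RYR3	9
RYR2	8
ZFHX3	7
ANK2	6
AKAP9	5
SYNE2	5
TRPM4	5
CACNA1D	4
CACNA1I	4
GNB3	4
MYH6	4
SCN5A	4
HCN4	3
KCNH2	3
SCN1A	3
SCN3A	3
CACNA1G	2
CACNB2	2
GJD3	2
NUP155	2
SCN4A	2
SCN10A	2
SYNP02L	2
ADRB2	1
C9orf3	1
CASQ2	1
CAV1	1
CAV3	1
ERG	1
HCN2	1
HCN3	1
ITPR1	1
KCNA4	1
KCNA5	1
KCND3	1
KCNN3	1
LMNA	1
PITX2	1
PKP2	1
PRKAG2	1
SCN1B	1
SCN4B	1
SCN9A	1
SLC8A1	1
SNTA1	1
SOX5	1
TBX3	1
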