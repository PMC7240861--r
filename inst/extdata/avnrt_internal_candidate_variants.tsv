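gene	hgvs_c	hgvs_p	transcript	translation	af_kg_eas	af_exac_eas	cases	controls
RYR2	c.4652A > G	p.Asn1551Ser	XM_005273224.1	missense	.	4.52E-03	1	0
RYR2	c.4094C > T	p.Ala1365Val	XM_005273224.1	missense	7.90E-03	4.21E-03	2	4
RYR2	c.7076G > A	p.Arg2359Gln	XM_005273224.1	missense	.	7.00E-04	1	0
RYR2	c.3143A > G	p.Asp1048Gly	XM_005273224.1	missense	.	.	1	0
RYR2	c.6040G > T	p.Asp2014Tyr	XM_005273224.1	missense	.	.	1	0
RYR2	c.5774T > C	p.Ile1925Thr	XM_005273224.1	missense	.	0	1	0
RYR2	c.11352T > G	p.Ile3784Met	XM_005273224.1	missense	.	.	1	0
RYR2	c.13050A > C	p.Leu4350Phe	XM_005273224.1	missense	.	.	0	1
RYR2	c.5923A > G	p.Met1975Val	XM_005273224.1	missense	.	2.34E-04	0	1
RYR2	c.5570C > T	p.Pro1857Leu	XM_005273224.1	missense	0	1.17E-46	1	0
RYR2	c.6092C > T	p.Ser2031Phe	XM_005273224.1	missense	.	1.16E-04	1	0
RYR2	c.3683C > A	p.Thr1228Asn	XM_005273224.1	missense	.	.	1	1
RYR2	c.3721G > A	p.Val1241Ile	XM_005273224.1	missense	2.00E-03	2.33E-04	0	1
SCN1A	c.3176A > T	p.Asp1059Val	NM_001165963.1	missense	.	3.52E-08	1	0
SCN1A	c.3053G > A	p.Arg1018Lys	NM_001165963.1	missense	.	2.32E-08	1	0
SCN1A	c.2141T > G	p.Met714Arg	NM_001165963.1	missense	.	.	1	0
SCN1A	c.135C > G	p.Asp45Glu	NM_001165963.1	missense	1.00E-03	8.09E-04	1	0
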