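gene	a1	f_a	f_u	a2	p	or	functional_class	hgvs_c	hgvs_p
SEMA6D	G	0.414	0.225	T	1.10E-4	2.44	intron	c.1646+105G > T	.
ROBO2	G	0.207	0.075	C	3.18E-4	3.23	intron	c.109+121G > C	.
MYL12A	C	0.161	0.041	CGT	3.48E-4	4.51	intron	c.199+192_199+193delGT	.
ABLIM2	T	0.177	0.345	C	3.49E-4	0.41	intron	c.838-131G > A	.
ATP2B2	G	0.000	0.060	A	7.05E-4	0.00	intron	c.397+71C > T	.
ATP2B2	A	0.110	0.025	G	1.02E-3	4.81	synonymous	c.1626C > T	p.Ile542Ile
ATP2B2	T	0.110	0.025	C	1.02E-3	4.81	intron	c.1659+102G > A	.
UNC5B	T	0.120	0.027	C	1.05E-3	4.89	intron	c.305-277C > T	.
NEO1	C	0.342	0.195	T	1.80E-3	2.14	intron	c.1511+90T > C	.
NEO1	TA	0.348	0.200	T	1.90E-3	2.13	utr	c.*52_*53insA	.
ATP2B2	T	0.183	0.325	G	2.62E-3	0.47	intron	c.1417-186C > A	.
NEO1	G	0.342	0.200	A	2.77E-3	2.07	synonymous	c.1779A > G	p.Lys593Lys
ASPH	C	0.518	0.359	A	2.80E-3	1.93	intron	c.1108-121T > G	.
ABLIM2	A	0.232	0.380	G	3.07E-3	0.49	intron	c.915+26C > T	.
PLXNB1	A	0.043	0.000	G	3.51E-3	NA	other	n.5120C > T	.
DPYSL2	T	0.108	0.028	C	3.56E-3	4.22	intron	c.936+251C > T	.
PLXNC1	T	0.043	0.000	C	3.65E-3	NA	intron	c.1062+161C > T	.
CACNA1G	CTGTGTGTGTGTTTGTG	0.049	0.140	C	4.41E-3	0.32	intron	c.5782-165_5782-164insTGTGTGTGTGTTTGTG	.
ASPH	C	0.488	0.340	G	5.26E-3	1.85	intron	c.1346-79C > G	.
UNC5B	T	0.134	0.050	C	5.31E-3	2.94	splice_site	c.732C > T	p.Tyr244Tyr
UNC5B	A	0.134	0.050	G	5.31E-3	2.94	intron	c.734-173G > A	.
UNC5B	G	0.134	0.050	A	5.31E-3	2.94	missense	c.724A > G	p.Ile242Val
UNC5B	CTG	0.134	0.050	C	5.31E-3	2.94	intron	c.1100-35_1100-34insTG	.
UNC5B	T	0.134	0.050	C	5.31E-3	2.94	intron	c.901+33C > T	.
ASPH	T	0.512	0.365	C	5.67E-3	1.83	intron	c.1195-57G > A	.
UNC5B	A	0.128	0.045	G	6.47E-3	3.12	intron	c.80-87G > A	.
EPHA2	CAG	0.041	0.000	C	6.82E-3	NA	intron	c.86-344_86-343dupCT	.
RYR3	C	0.073	0.015	G	6.92E-3	5.18	synonymous	c.2403G > C	p.Leu801Leu
RYR3	G	0.073	0.015	A	6.92E-3	5.18	intron	c.3556+34A > G	.
RYR2	A	0.061	0.010	G	7.78E-3	6.43	intron	c.13317+48G > A	.
RYR3	C	0.370	0.240	G	7.95E-3	1.86	intron	c.5861-174C > G	.
PLXNA4	CACACACAAACAT	0.024	0.095	C	8.05E-3	0.24	intron	c.3874+275_3874+276insATGTTTGTGTGT	.
SEMA5A	C	0.352	0.223	T	8.65E-3	1.89	intron	c.1599+327G > A	.
RYR1	G	0.012	0.070	A	8.74E-3	0.17	intron	c.11689+68A > G	.
SLIT3	G	0.253	0.383	A	9.35E-3	0.55	intron	c.1459+4296C > T	.
RYR2	G	0.438	0.299	A	9.66E-3	1.82	intron	c.9128+133A > G	.
FES	T	0.037	0.11	C	9.71E-3	0.31	other	n.616T > C	.
FES	A	0.037	0.11	G	9.71E-3	0.31	intron	c.388-212A > G	.
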