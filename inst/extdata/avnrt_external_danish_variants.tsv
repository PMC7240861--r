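gene	hgvs_c	hgvs_p	transcript	translation	maf_exac	maf_d2k	allele_count	cohort_label
RYR2	c.4652A > G	p.Asn1551Ser	ENST00000366574	missense	3.50E-04	5.00E-04	1	danish_avnrt
RYR2	c.1088T > C	p.Ile363Thr	ENST00000366574	missense	0	0	1	danish_avnrt
RYR2	c.1115T > A	p.Leu372His	ENST00000366574	missense	1.00E-05	2.50E-04	1	danish_avnrt
RYR2	c.1250G > A	p.Arg417Gln	ENST00000366574	missense	2.00E-05	0.00E+00	2	danish_avnrt
RYR2	c.2828T > C	p.Leu943Ser	ENST00000366574	missense	2.30E-04	0.00E+00	1	danish_avnrt
RYR2	c.3251G > A	p.Arg1084Lys	ENST00000366574	missense	1.50E-04	7.50E-04	1	danish_avnrt
RYR2	c.5186T > C	p.Met1729Thr	ENST00000366574	missense	0	0	1	danish_avnrt
RYR2	c.8162T > C	p.Ile2721Thr	ENST00000366574	missense	5.70E-04	4.13E-03	1	danish_avnrt
RYR2	c.10468G > T	p.Ala3490Ser	ENST00000366574	missense	0	2.50E-04	1	danish_avnrt
RYR2	c.10528C > A	p.Arg3510Ser	ENST00000366574	missense	3.00E-05	2.50E-04	1	danish_avnrt
RYR2	c.10846G > T	p.Ala3616Ser	ENST00000366574	missense	0	0	1	danish_avnrt
SCN1A	c.3521C > G	p.Thr1174Ser	ENST00000303395	missense	1.77E-03	3.25E-03	2	danish_avnrt
SCN1A	c.1625G > A	p.Arg542Gln	ENST00000303395	missense	1.53E-03	1.75E-03	1	danish_avnrt
SCN1A	c.1199T > C	p.Met400Thr	ENST00000303395	missense	0	0	1	danish_avnrt
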