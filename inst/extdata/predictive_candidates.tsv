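gene	pv_pikespeak	fdr_pikespeak	log2fc_pikespeak	pv_chamber	fdr_chamber	log2fc_chamber
DUSP2	1.51e-05	1.89e-01	0.890	3.45e-03	1	0.760
HLA-DQA1	2.71e-05	3.39e-01	-1.161	5.68e-03	1	-0.957
COL5A3	3.20e-05	4.00e-01	-1.510	1.06e-02	1	-0.921
TNNT1	3.65e-05	4.57e-01	1.176	1.07e-07	1.34e-03	2.077
KIF19	1.37e-04	1	1.128	2.20e-04	1	1.447
C1QB	6.71e-04	1	-1.158	3.76e-02	1	-0.935
DDX11L2	1.03e-03	1	-1.004	2.86e-03	1	-1.352
ZNF595	1.25e-03	1	-0.778	8.33e-03	1	-0.988
DRAXIN	1.11e-02	1	-0.836	1.29e-02	1	-1.096
FOLR3	2.15e-02	1	-0.822	5.54e-09	6.94e-05	-2.635
S100B	4.05e-02	1	-0.782	1.02e-04	1	-2.041
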