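gene	pv_pikespeak	fdr_pikespeak	log2fc_pikespeak	pv_chamber	fdr_chamber	log2fc_chamber
ISG15	1.95e-03	1	-0.851	2.38e-05	0.103	-1.260
HLA-DQB1	1.08e-05	0.136	-1.092	2.11e-03	1	-0.773
LOC101927999	9.64e-05	1	-1.313	3.15e-03	1	-0.728
HBA2	1.50e-04	1	3.091	1.53e-02	1	0.841
HBA1	2.08e-04	1	3.483	2.64e-03	1	1.153
FOLR3	1.65e-03	1	-1.183	1.35e-11	1.69e-07	-2.923
SIGLEC1	4.91e-03	1	-0.959	2.08e-12	2.60e-08	-2.545
GAS6	5.28e-03	1	-0.843	1.62e-02	1	-0.861
TNNT1	2.77e-02	1	0.755	7.54e-06	9.41e-02	1.952
DRAXIN	3.74e-02	1	-0.818	2.05e-03	1	-1.267
PDE5A	4.43e-02	1	0.755	1.99e-03	1	1.145
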