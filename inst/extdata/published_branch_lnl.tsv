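family	neg_lnl_null	omega_null	neg_lnl_alt	omega_grass	omega_eudicot
HK	11783.30	0.10	11785.01	0.10	0.13
NI	16479.90	0.06	16479.89	0.06	0.07
SPS	19549.54	0.10	19549.53	0.10	0.14
SUSY	23700.03	0.09	23700.04	0.08	0.09
SUT_type1	10101.69	0.12	100094.07	NA	0.14
SUT_type2	5594.01	0.29	5599.79	0.14	0.48
SUT_type4	4056.79	0.35	4107.06	0.10	0.76
PMT	13163.31	0.11	13172.08	0.14	0.07
STP	13959.40	0.07	13903.48	0.11	0.05
ERD6-like	10500.44	0.56	10614.28	0.33	0.14
pGlcT	10476.77	0.11	10480.65	0.14	0.11
INT	7717.63	0.08	7722.22	0.10	0.03
TMT	11508.87	0.11	11308.87	0.11	0.16
VGT	9974.43	0.14	9797.18	0.13	0.15
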