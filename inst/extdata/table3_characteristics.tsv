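variable	level	controls	cases	printed_p
sex	female	1828	251	0.34
sex	male	1867	280	0.34
race_ethnicity	nh_white	1344	191	0.003
race_ethnicity	nh_black	430	54	0.003
race_ethnicity	hispanic	1773	280	0.003
race_ethnicity	other	138	5	0.003
birthplace	united_states	2592	355	0.05
birthplace	mexico	785	145	0.05
birthplace	other	306	27	0.05
age	lt20	501	76	0.32
age	20_24	1099	158	0.32
age	25_29	966	141	0.32
age	30_34	754	119	0.32
age	35_39	323	31	0.32
age	ge40	52	8	0.32
education	lt_high_school	1155	188	0.06
education	high_school	1195	169	0.06
education	gt_high_school	1292	160	0.06
parity	0	1314	190	0.79
parity	1	1170	157	0.79
parity	2	679	95	0.79
parity	3plus	396	62	0.79
smoking	no	3447	505	0.15
smoking	yes	225	24	0.15
poverty	low	922	100	0.02
poverty	medium_low	925	144	0.02
poverty	medium_high	925	137	0.02
poverty	high	925	152	0.02
season	spring	807	106	0.45
season	summer	798	127	0.45
season	fall	876	122	0.45
season	winter	887	116	0.45
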