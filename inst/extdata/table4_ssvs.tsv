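pollutant	level	cutoff_low	cutoff_high	cases	controls	or	ci_low	ci_high	bayes_factor
quinoline	low	NA	6.50e-14	18	176	1.00	NA	NA	NA
quinoline	medium	6.50e-14	1.71e-05	434	3149	1.42	0.87	2.42	0.32
quinoline	high	1.71e-05	NA	39	178	2.06	1.11	3.87	1.01
trichloroethylene	low	NA	0.0524	13	176	1.00	NA	NA	NA
trichloroethylene	medium	0.052	0.16	460	3151	2.00	1.14	3.61	3.79
trichloroethylene	high	0.16	NA	18	176	1.32	0.61	2.80	0.60
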