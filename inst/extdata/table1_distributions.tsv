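pollutant	mean	median	p5	p25	p75	p95
acetaldehyde	1.50	1.45	0.62	0.86	1.93	2.97
acrolein	0.11	0.09	0.01	0.04	0.14	0.32
acrylonitrile	4.08e-03	1.80e-04	4.18e-06	4.00e-05	7.80e-04	2.41e-02
arsenic compounds	6.00e-05	2.00e-05	1.18e-06	1.00e-05	5.00e-05	1.40e-04
benzene	1.40	1.26	0.45	0.85	1.73	2.83
beryllium compounds	1.00e-05	1.00e-05	4.53e-07	2.06e-06	1.00e-05	2.00e-05
1,3-butadiene	0.13	0.12	0.01	0.07	0.17	0.30
cadmium compounds	1.00e-04	2.00e-05	8.08e-07	4.52e-06	5.00e-05	2.20e-04
carbon tetrachloride	0.28	0.27	0.27	0.27	0.27	0.29
chloroform	0.08	0.07	0.04	0.05	0.09	0.16
chromium VI	3.40e-04	7.00e-05	2.65e-06	2.00e-05	2.10e-04	1.42e-03
1,3-dichloropropene	0.08	0.07	0.01	0.04	0.11	0.17
diesel particulate matter	1.18	0.97	0.28	0.53	1.42	2.81
ethylene oxide	1.19e-02	8.25e-03	7.80e-04	4.35e-03	1.42e-02	3.38e-02
ethylene dibromide	2.57e-02	2.98e-02	4.00e-04	1.93e-02	3.58e-02	3.73e-02
ethylene dichloride	0.05	0.05	0.01	0.03	0.05	0.10
formaldehyde	1.60	1.57	0.55	1.02	2.01	2.97
hexachlorobenzene	3.00e-05	4.15e-07	1.08e-07	2.38e-07	1.08e-06	6.00e-06
hydrazine	1.00e-05	2.74e-09	2.88e-15	2.31e-10	6.14e-08	4.00e-05
lead compounds	2.49e-03	1.73e-03	7.00e-05	4.90e-04	3.07e-03	7.02e-03
manganese compounds	1.50e-03	6.40e-04	1.00e-05	1.00e-04	1.37e-03	4.60e-03
mercury compounds	1.63e-03	1.52e-03	1.50e-03	1.51e-03	1.57e-03	1.99e-03
methylene chloride	0.49	0.48	0.11	0.33	0.63	0.88
nickel compounds	7.30e-04	4.10e-04	2.00e-05	1.30e-04	8.00e-04	2.39e-03
polychlorinated biphenyls	4.00e-04	3.90e-04	3.80e-04	3.80e-04	4.00e-04	4.70e-04
perchloroethylene	0.20	0.20	0.02	0.12	0.27	0.38
polycyclic organic matter	7.73e-03	6.58e-03	1.55e-03	4.07e-03	9.63e-03	1.78e-02
propylene dichloride	2.15e-02	2.42e-02	6.64e-03	1.80e-02	2.77e-02	2.80e-02
quinoline	1.00e-05	2.70e-08	9.65e-14	4.92e-09	2.92e-07	2.00e-05
1,1,2,2-tetrachloroethane	0.06	0.07	0.02	0.05	0.08	0.08
trichloroethylene	0.10	0.09	0.05	0.07	0.11	0.16
vinyl chloride	6.42e-02	6.60e-02	1.04e-03	4.36e-02	7.93e-02	1.19e-01
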