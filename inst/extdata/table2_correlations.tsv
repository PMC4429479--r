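pollutant	acetaldehyde	acrolein	formaldehyde	benzene	methylene chloride	ethylene dibromide	propylene dichloride	1,1,2,2-tetrachloroethane	ethylene dichloride	vinyl chloride	diesel particulate matter	nickel compounds
acetaldehyde	1.00	0.97	0.98	0.85	0.79	0	0	0	0	0	0	0
acrolein	0.97	1.00	0.95	0.81	0.68	0	0	0	0	0	0	0
formaldehyde	0.98	0.95	1.00	0.89	0.82	0	0	0	0	0	0	0
benzene	0.85	0.81	0.89	1.00	0.74	0	0	0	0	0	0	0
methylene chloride	0.79	0.68	0.82	0.74	1.00	0	0	0	0	0	0	0
ethylene dibromide	0	0	0	0	0	1.00	0.98	1.00	0	0	0	0
propylene dichloride	0	0	0	0	0	0.98	1.00	0.99	0	0	0	0
1,1,2,2-tetrachloroethane	0	0	0	0	0	1.00	0.99	1.00	0	0	0	0
ethylene dichloride	0	0	0	0	0	0	0	0	1.00	0.98	0	0
vinyl chloride	0	0	0	0	0	0	0	0	0.98	1.00	0	0
diesel particulate matter	0	0	0	0	0	0	0	0	0	0	1.00	0.87
nickel compounds	0	0	0	0	0	0	0	0	0	0	0.87	1.00
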