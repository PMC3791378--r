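tfNcFull	kAssocNc	coveredPct	tfNcSub	kLacI1	kLacI10	kLacI100	kLacI1000	obstacles
0	1800	0	0	4.19	4.04	4.11	4.19	mobile
10000	2000	9	216	4.58	4.63	4.67	4.74	mobile
30000	2571	26	647	6.11	6.10	6.19	6.32	mobile
50000	3600	42	1078	8.63	8.76	8.73	8.88	mobile
70000	6000	55	1509	13.15	13.05	13.06	13.26	mobile
40000	NA	40	863	7.37	7.37	7.37	7.37	immobile
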