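genome_id	completeness	contamination
culture001	93.51	2.03
culture002	97.86	0.71
culture003	98.06	3.58
culture004	93.27	0.48
culture005	96.04	1.7
culture006	99.04	0.81
culture007	99.3	1.34
culture008	99.54	2.35
culture009	97.08	1.94
culture010	92.37	2.91
culture011	98.85	3.26
culture012	92.52	2.35
culture013	92.62	1.95
culture014	98.99	1.61
culture015	98.59	0.17
culture016	94.47	3.68
culture017	94.47	3.29
culture018	93.47	3.21
culture019	98.94	3.6
culture020	96.21	3.3
culture021	99.09	1.7
culture022	98.26	0.3
culture023	97.83	3.34
culture024	92.26	1.12
culture025	94.29	2.69
culture026	92.79	3.77
culture027	93.82	2.66
culture028	97.12	3.33
culture029	98.91	0.3
culture030	92.78	3.4
culture031	98.72	3.51
culture032	93.29	0.86
culture033	96.76	1.82
culture034	94.67	1.41
culture035	97.84	1
culture036	98.19	2.2
culture037	81.35	95.21
culture038	98.74	1.39
culture039	97.13	0.11
culture040	92.93	1.56
culture041	93.89	1.8
culture042	98.33	0.32
culture043	98.77	3.95
culture044	95.29	0.71
culture045	99.14	1.27
culture046	94.07	2.68
culture047	99.53	2.46
culture048	99.15	2.12
culture049	93.59	0
culture050	98.92	3.56
culture051	95.2	1.55
culture052	97.44	0.81
culture053	94.54	2.05
culture054	94.03	0.54
culture055	94.69	1.68
culture056	96.25	1.22
culture057	94.35	2.32
culture058	93.29	2.05
culture059	92.95	3.82
culture060	95.87	3.81
culture061	99.06	1.47
culture062	32.48	1.07
culture063	96.8	3.37
culture064	93.11	1.37
culture065	98.02	0.87
culture066	92.24	0.84
culture067	94.92	2.07
culture068	95.59	1.21
culture069	97.5	0.66
culture070	94.82	0.89
culture071	93.96	1.08
culture072	92.68	0.1
culture073	97.38	2.69
culture074	98.32	2.56
culture075	92.86	1.23
culture076	96.27	3.99
culture077	97.34	3.24
culture078	92.21	0.05
culture079	96.59	0.19
culture080	93.13	3.56
culture081	92.22	3.62
culture082	94.02	0.96
culture083	97.95	1.94
culture084	98.96	1.01
culture085	96.49	3.59
culture086	94.44	2.68
culture087	95.96	2.9
culture088	96.21	1.59
culture089	94.47	3.13
culture090	95.03	1.45
culture091	97.76	2.01
culture092	95.13	0.49
culture093	94.42	0.58
culture094	96.7	3.69
culture095	97.4	2.62
culture096	94.36	0.8
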