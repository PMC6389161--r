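accession	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
ARGP820101	0.61	1.07	0.46	0.47	2.02	0.07	0.61	2.22	1.15	1.53	1.18	0.06	1.95	0	0.6	0.05	0.05	1.32	2.65	1.88
BULH740101	-0.2	-0.45	-0.2	-0.3	-2.33	0	-0.12	-2.26	-0.35	-2.46	-1.47	0.08	-0.98	0.16	-0.12	-0.39	-0.52	-1.56	-2.01	-2.24
CHAM820102	-0.368	4.53	2.06	1.77	1.06	-0.525	0	0.791	0	1.07	0.656	0	-2.24	0.731	-1.03	-0.524	0	0.401	1.6	4.91
CHAM830107	0	0	1	1	0	1	0	0	0	0	0	1	0	0	0	0	0	0	0	0
CHAM830108	0	1	0	0	1	0	1	0	1	0	1	1	0	1	1	0	0	0	1	1
CIDH920101	-0.45	0.79	-1.52	-0.8	1.48	-1	1.07	0.76	-0.36	1.29	1.37	-0.2	-0.12	-0.99	-0.24	-0.98	-0.7	1.26	1.38	1.49
CIDH920102	-0.08	0.76	-0.71	-1.31	1.53	-0.84	0.43	1.39	-0.09	1.24	1.27	-0.7	-0.01	-0.4	-0.09	-0.93	-0.59	1.09	2.25	1.53
CIDH920103	0.36	0.7	-1.09	-0.83	1.01	-0.82	0.16	2.17	-0.56	1.18	1.21	-0.9	-0.06	-1.05	-0.52	-0.6	-1.2	1.21	1.31	1.05
CIDH920104	0.17	1.24	-1.05	-1.19	1.29	-0.57	-0.25	2.06	-0.62	0.96	0.6	-0.9	-0.21	-1.2	-0.7	-0.83	-0.62	1.21	1.51	0.66
CIDH920105	0.02	0.77	-1.04	-1.14	1.35	-0.8	0.26	1.81	-0.41	1.14	1	-0.77	-0.09	-1.1	-0.42	-0.97	-0.77	1.13	1.71	1.11
EISD840101	0.25	0.04	-0.72	-0.62	0.61	0.16	-0.4	0.73	-1.1	0.53	0.26	-0.64	-0.07	-0.69	-1.76	-0.26	-0.18	0.54	0.37	0.02
EISD860101	0.67	0.38	-1.2	-0.76	2.3	0	0.64	1.9	-0.57	1.9	2.4	-0.6	1.2	-0.22	-2.1	0.01	0.52	1.5	2.6	1.6
EISD860102	0	0.17	1.9	3	1.1	0	0.99	1.2	5.7	1	1.9	1.3	0.18	1.9	10	0.73	1.5	0.48	1.6	1.8
EISD860103	0	0.76	-0.98	-0.89	0.92	0	-0.75	0.99	-0.99	0.89	0.94	-0.86	0.22	-1	-0.96	-0.67	0.09	0.84	0.67	-0.93
FAUJ830101	0.31	1.54	-0.77	-0.64	1.79	0	0.13	1.8	-0.99	1.7	1.23	-0.6	0.72	-0.22	-1.01	-0.04	0.26	1.22	2.25	0.96
GOLD730101	0.75	1	0	0	2.65	0	0	2.95	1.5	2.4	1.3	0.69	2.6	0.59	0.75	0	0.45	1.7	3	2.85
GUYH850101	0.1	-1.42	0.78	0.83	-2.12	0.33	-0.5	-1.13	1.4	-1.18	-1.59	0.48	0.73	0.95	1.91	0.52	0.07	-1.27	-0.51	-0.21
JANJ790102	0.3	0.9	-0.6	-0.7	0.5	0.3	-0.1	0.7	-1.8	0.5	0.4	-0.5	-0.3	-0.7	-1.4	-0.1	-0.2	0.6	0.3	-0.4
JOND750101	0.87	1.52	0.66	0.67	2.87	0.1	0.87	3.15	1.64	2.17	1.67	0.09	2.77	0	0.85	0.07	0.07	1.87	3.77	2.67
LAWE840101	-0.48	-0.32	-0.75	-0.71	1.03	0	-0.51	0.81	-0.09	1.02	0.81	-0.87	2.03	-0.32	-0.06	0.05	-0.35	0.56	0.66	1.24
LEVM760101	-0.5	-1	2.5	2.5	-2.5	0	-0.5	-1.8	3	-1.8	-1.3	0.2	-1.4	0.2	3	0.3	-0.4	-1.5	-3.4	-2.3
MANP780101	12.97	14.63	10.85	11.89	14	12.43	12.16	15.67	11.36	14.9	14.39	11.42	11.37	11.76	11.72	11.23	11.69	15.71	13.93	13.42
MIYS850101	2.36	3.36	1.67	1.74	4.37	2.06	2.41	4.17	1.23	3.93	4.22	1.7	1.89	1.75	1.92	1.81	2.04	3.49	3.82	2.91
NOZY710101	0.5	0	0	0	2.5	0	0.5	1.8	0	1.8	1.3	0	0	0	0	0	0.4	1.5	3.4	2.3
OOBM770101	-1.895	-2.035	-1.518	-1.535	-1.864	-1.898	-1.755	-1.951	-1.374	-1.966	-1.963	-1.56	-1.699	-1.521	-1.475	-1.753	-1.767	-1.981	-1.869	-1.686
OOBM770102	-1.404	-1.365	-1.162	-1.163	-1.135	-1.364	-1.215	-1.189	-1.074	-1.315	-1.303	-1.178	-1.236	-1.116	-0.921	-1.297	-1.252	-1.254	-1.03	-1.03
OOBM770103	-0.491	-0.67	-0.356	-0.371	-0.729	-0.534	-0.54	-0.762	-0.3	-0.65	-0.659	-0.382	-0.463	-0.405	-0.554	-0.455	-0.515	-0.728	-0.839	-0.656
OOBM770104	-9.475	-12.21	-12.144	-13.815	-20.504	-7.592	-17.55	-15.608	-12.366	-15.728	-15.704	-12.48	-11.893	-13.689	-16.225	-10.518	-12.369	-13.867	-26.166	-20.232
OOBM770105	-7.02	-8.19	-9.296	-10.467	-12.485	-5.456	-12.15	-9.512	-9.666	-10.52	-10.424	-9.424	-8.652	-10.044	-10.131	-7.782	-8.764	-8.778	-14.42	-12.36
OOBM850103	0.46	0.2	-0.33	0.48	0.52	0.64	-1.31	3.28	-1.71	0.43	0.15	1.31	-0.58	-1.12	-1.54	-0.83	-1.52	0.54	1.25	-2.21
OOBM850104	-2.49	-3.13	8.86	4.04	-6.64	-0.56	4.22	-10.87	-9.97	-7.16	-4.96	2.27	5.19	1.79	2.55	-1.6	-4.75	-3.97	-17.84	9.25
PONP800101	12.28	14.93	10.97	11.19	13.43	12.01	12.84	14.77	10.8	14.1	14.33	11	11.19	11.28	11.49	11.26	11.65	15.07	12.95	13.29
PONP800102	7.62	10.93	6.18	6.38	8.99	7.31	7.85	9.99	5.72	9.37	9.83	6.17	6.64	6.67	6.81	6.93	7.08	10.38	8.41	8.53
PONP800103	2.63	3.36	2.29	2.31	3.02	2.55	2.57	3.08	2.12	2.98	3.18	2.27	2.46	2.45	2.45	2.6	2.55	3.21	2.85	2.79
PONP800104	13.65	14.49	10.98	12.55	14.08	15.36	11.59	14.63	11.96	14.01	13.4	12.24	11.51	11.3	11.28	11.26	13	12.88	12.06	12.64
PONP800105	14.6	15.9	13.78	13.59	14.18	14.18	15.35	14.1	13.28	16.49	16.23	11.79	14.1	12.02	13.24	13.36	14.5	16.3	13.9	14.76
PONP800106	10.67	14.15	10.21	11.71	13.27	10.95	12.07	12.95	9.93	13.07	15	10.85	10.62	11.71	11.05	11.18	10.53	13.86	11.41	11.52
PRAM900101	-6.7	-8.4	38.5	34.3	-15.5	-4.2	12.6	-13	36.8	-11.7	-14.2	20.1	0.8	17.2	51.5	-2.5	-5	-10.9	-7.9	2.9
RADA880101	1.81	1.28	-8.72	-6.81	2.98	0.94	-4.66	4.92	-5.55	4.92	2.35	-6.64	0	-5.54	-14.92	-3.4	-2.57	4.04	2.33	-0.14
RADA880102	0.52	0	0	-0.79	2.09	0	0.95	2.04	0.08	1.76	1.32	-0.01	0	-0.07	-1.32	0.04	0.27	1.18	2.51	1.63
RADA880103	0.13	-2.52	-2.23	-3.43	-3.74	1.45	-5.61	-2.77	-3.97	-2.64	-3.83	-3.04	0	-3.84	-5	-1.66	-2.31	-2.05	-8.21	-5.97
RADA880104	1.29	0	0	-6.02	0.89	0.94	-5.61	2.88	-5.63	3.16	1.03	-6.63	0	-5.47	-13.6	-3.44	-2.84	2.86	-0.18	-1.77
RADA880105	1.42	0	0	-9.45	-2.85	2.39	-11.22	0.11	-9.6	0.52	-2.8	-9.67	0	-9.31	-18.6	-5.1	-5.15	0.81	-8.39	-7.74
RADA880107	-0.29	0	-1.02	-0.9	0	-0.34	-0.94	0.24	-2.05	-0.12	-0.24	-1.18	0	-1.53	-2.71	-0.75	-0.71	0.09	-0.59	-1.02
ROBB790101	-1	2.1	-1.2	-0.7	2.8	0.3	1.1	4	-0.9	2	1.8	-0.7	0.4	-0.1	0.3	-1.2	-0.5	1.4	3	2.1
ROSG850101	86.6	132.3	97.8	113.9	194.1	62.9	155.8	158	115.5	164.1	172.9	103.3	92.9	119.2	162.2	85.6	106.5	141	224.6	177.7
SIMZ760101	0.73	0.7	0.54	0.55	2.65	0	1.1	2.97	1.5	2.49	1.3	-0.01	2.6	-0.1	0.73	0.04	0.44	1.69	3	2.97
SWER830101	-0.4	0.17	-1.31	-1.22	1.92	-0.67	-0.64	1.25	-0.67	1.22	1.02	-0.92	-0.49	-0.91	-0.59	-0.55	-0.28	0.91	0.5	1.67
VHEG790101	-12.04	3.95	23.22	16.81	-21.98	-7.85	6.28	-18.32	9.71	-17.79	-8.86	4.25	5.82	2.16	39.23	-1.54	-4.15	-16.22	-16.19	-1.51
WERD780102	0.16	-0.12	-0.24	-0.45	-0.25	-0.16	-0.18	-0.19	-0.12	-0.44	-0.79	1.03	-0.59	-0.55	-0.2	-0.01	0.05	-0.46	-0.33	-0.42
WERD780103	0.15	-0.19	-0.22	0.14	1.18	0.36	-0.25	0.02	-0.16	0.06	0.11	0.69	0.11	-0.06	-0.37	0.13	0.28	-0.08	-0.12	0.19
WERD780104	-0.07	0.17	-0.8	-0.63	0.4	0.27	-0.49	0.06	-0.45	-0.17	0.03	-0.57	-0.47	-0.26	-0.4	-0.11	0.09	-0.11	-0.61	-0.61
YUTK870101	8.5	11	8.5	8.8	11.2	7.1	10.1	16.8	7.9	15	13.3	8.2	8.2	6.3	0	7.4	8.8	12	9.9	8.8
YUTK870102	6.8	8.3	7	4.9	8.3	6.4	9.2	10	7.5	12.2	8.4	6.2	6.9	8.5	0	8	7	9.4	5.7	6.8
YUTK870103	18.08	18.17	17.36	18.16	17.3	18.24	18.49	18.62	17.96	18.6	18.11	17.47	18.16	17.93	0	17.57	17.54	18.3	17.19	17.99
YUTK870104	18.56	17.84	17.94	17.97	17.95	18.57	18.64	19.21	18.36	19.01	18.49	18.24	18.77	18.51	0	18.06	17.71	18.98	16.87	18.23
ZIMJ680101	0.83	1.48	0.64	0.65	2.75	0.1	1.1	3.07	1.6	2.52	1.4	0.09	2.7	0	0.83	0.14	0.54	1.79	0.31	2.97
MUNV940101	0.423	0.877	0.87	0.167	0.706	1.162	0.802	0.566	0.615	0.494	0.444	0.906	1.945	0.594	0.503	0.928	0.884	0.706	0.69	0.778
MUNV940102	0.619	1.107	0.932	0.675	0.968	1.361	1.034	0.876	0.784	0.74	0.736	1.089	1.78	0.77	0.753	0.969	1.053	0.939	0.91	1.009
MUNV940103	1.08	0.733	1.266	1.085	0.685	1.104	0.906	0.583	1.026	0.789	0.812	1.197	1.412	1.05	0.976	0.987	0.784	0.546	0.755	0.665
MUNV940104	0.978	0.573	1.038	0.962	0.585	1.405	0.724	0.502	0.841	0.766	0.729	0.915	2.613	0.863	0.784	0.784	0.569	0.444	0.671	0.56
MUNV940105	1.4	1.14	1.89	1.42	1.07	2.06	1.25	1.02	1.34	1.33	1.12	1.61	3.9	1.33	1.23	1.2	0.99	0.87	1.1	0.98
WIMW960101	4.08	4.49	3.02	2.23	5.38	4.24	4.08	4.52	3.77	4.81	4.48	3.83	3.8	3.67	3.91	4.12	4.11	4.18	6.1	5.19
PONP930101	0.85	2.1	-1.1	-0.79	1.69	0	0.22	3.14	-1.19	1.99	1.42	-0.48	-1.14	-0.42	0.2	-0.52	-0.08	2.53	1.76	1.37
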