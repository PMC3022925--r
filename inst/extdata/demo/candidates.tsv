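gene_id	position	ref	alt	d	D	w	Q	n	ambiguous
G001	240	C	T	38	40	0.291	91.8	71.9	FALSE
G001	228	G	C	6	140	0.578	78.5	61	FALSE
G001	92	G	C	40	171	1.049	52	54.1	FALSE
G001	109	A	T	9	197	1.448	5.8	70.6	TRUE
G001	222	C	T	27	106	0.821	58.7	84.6	FALSE
G001	123	G	T	55	387	0.67	19.5	72.7	FALSE
G001	295	C	T	46	201	0.316	92.6	41.6	FALSE
G002	57	C	A	15	110	0.452	95.8	90.3	FALSE
G002	6	G	T	27	118	1.443	66.3	45.8	FALSE
G002	51	C	T	19	212	0.669	80.9	91.8	FALSE
G002	93	T	C	19	203	1.436	96.2	55.6	FALSE
G002	24	C	T	43	79	1.061	60.7	85.7	FALSE
G003	129	G	A	19	239	0.664	54.6	77	FALSE
G003	357	T	C	16	253	0.639	4.5	66.9	FALSE
G003	171	A	G	17	104	3.639	69	61.9	FALSE
G003	398	T	G	31	53	1.352	67.9	91	FALSE
G003	183	C	T	29	54	0.562	60.5	53.2	FALSE
G003	333	C	T	52	121	1.434	44.4	46.7	FALSE
G003	48	C	T	37	207	1.245	92.8	46.2	FALSE
G003	204	A	G	54	178	1.908	31.1	96.8	FALSE
G004	238	G	T	1	119	1.236	88.9	87.2	FALSE
G004	141	G	A	1	100	2.389	77.3	47.6	FALSE
G004	69	G	T	5	288	1.108	74.6	54.9	FALSE
G004	24	C	T	26	159	0.162	67.5	66.8	FALSE
G004	51	G	A	2	146	0.436	52.3	3.8	FALSE
G005	10	A	C	29	119	0.904	77.4	79.8	FALSE
G005	48	C	A	60	177	1.365	85.7	61.7	FALSE
G005	138	A	T	40	249	1.107	82.8	83.3	FALSE
G006	24	T	A	22	217	1.211	69.3	55.7	FALSE
G006	157	G	A	28	119	1.192	79.2	95.9	FALSE
G006	128	T	A	14	25	1.032	93.9	57.7	TRUE
G006	153	C	T	56	208	0.937	77.3	46.8	FALSE
G006	348	A	T	17	59	1.33	90	62.3	TRUE
G007	126	G	A	31	239	0.572	89.2	88	FALSE
G007	27	G	A	1	235	0.945	77.7	44.8	FALSE
G007	9	A	G	35	120	2.529	61.8	0.3	FALSE
G007	39	T	C	48	66	0.202	94.1	78.9	FALSE
G007	192	G	A	47	212	0.534	80.8	95.9	FALSE
G008	294	T	C	47	114	0.14	86.4	54	FALSE
G008	57	C	T	43	142	1.292	68	70.8	FALSE
G008	352	A	C	13	80	1.333	59.3	71.2	FALSE
G009	105	C	G	46	128	1.163	78.1	93.1	FALSE
G009	126	A	G	13	113	0.38	96.3	80.7	FALSE
G009	174	A	G	59	121	0.963	80.6	72	FALSE
G009	41	T	C	39	351	1.203	74.9	28.7	FALSE
G009	87	G	A	28	146	0.953	11.4	60.2	TRUE
G009	167	C	T	53	103	0.334	10.5	43.4	FALSE
G009	30	A	G	25	43	0.857	78	96	FALSE
G009	36	A	T	27	160	0.547	12.2	81.3	FALSE
G009	15	G	A	59	98	1.296	53.6	45.7	FALSE
G010	179	C	G	37	180	0.097	91.1	91.5	FALSE
G010	270	A	G	35	133	0.925	78	52.6	FALSE
G010	153	T	C	3	305	0.792	51.5	56.3	FALSE
G010	143	C	A	41	258	0.633	58.8	47	FALSE
G010	262	G	A	13	182	0.7	61.7	68	FALSE
G011	312	T	C	54	250	0.576	64.5	68.6	FALSE
G011	75	T	C	49	68	0.607	91.4	44.2	FALSE
G011	54	C	T	30	87	1.438	83	0.5	TRUE
G011	342	T	A	33	209	1.974	45.1	42.2	FALSE
G011	26	A	G	0	269	0.471	72.7	65.8	FALSE
G012	312	C	T	36	104	0.659	94.7	35.5	TRUE
G012	195	T	A	29	181	0.295	67	31.7	FALSE
G013	72	C	T	31	166	1.117	89.2	71.3	TRUE
G013	244	C	A	50	95	1.242	19.2	91.6	FALSE
G013	102	G	T	43	249	0.758	84.5	35.3	TRUE
G014	286	G	C	47	279	2.422	97	42	FALSE
G014	384	C	G	36	205	3.235	67.3	44	FALSE
G014	324	C	A	53	235	0.928	87.5	12.7	TRUE
G014	200	T	C	14	75	0.498	84.8	92.9	FALSE
G014	393	A	C	53	308	2.662	53.1	78.9	FALSE
G014	366	G	C	14	104	1.243	95.6	78	FALSE
G014	228	G	A	11	385	0.437	64.5	94.1	FALSE
G014	127	C	T	21	24	2.785	49.2	74.8	FALSE
G014	255	G	A	9	174	0.357	82.6	56.6	FALSE
G014	390	A	G	11	226	1.159	71.7	74.9	FALSE
G014	288	C	T	0	77	0.457	66.7	60.6	FALSE
G014	46	C	G	37	296	0.584	94.4	73.3	FALSE
G015	201	G	T	0	243	1.213	86	86.5	FALSE
G015	241	C	A	1	80	0.493	48.2	53.1	FALSE
G015	135	G	A	3	146	0.099	86.8	44.2	TRUE
G015	84	T	G	38	178	0.044	58.6	91.6	FALSE
G015	402	T	G	14	31	0.904	43.8	7.9	FALSE
G015	108	C	T	6	239	0.144	71.3	73.7	FALSE
G016	270	T	A	28	157	0.672	59.5	69.7	FALSE
G016	258	T	C	43	43	1.738	9.6	42	FALSE
G017	279	A	T	0	73	0.679	85.3	57.6	FALSE
G017	306	T	C	43	82	0.24	38.5	62	FALSE
G017	29	T	C	38	194	0.145	65.3	79.2	FALSE
G017	326	A	G	25	171	1.016	67.1	50	TRUE
G017	30	G	C	60	238	0.099	31.5	10.3	FALSE
G017	229	G	T	31	184	1.331	78.8	53	FALSE
G018	6	T	C	30	321	0.53	77.8	25.9	FALSE
G018	99	G	A	10	163	3.884	58.2	68.2	FALSE
G018	133	C	G	4	214	0.936	51.7	8.4	FALSE
G018	126	C	T	20	103	0.932	82.2	63.6	FALSE
G018	81	G	A	18	393	3.344	68.3	78.6	FALSE
G019	400	C	A	52	184	0.284	62.3	46.2	TRUE
G019	306	G	A	3	80	1.278	72.2	53.7	FALSE
G019	66	T	A	4	357	0.173	62.5	86.7	FALSE
G019	423	A	G	5	6	0.645	90	93.6	TRUE
G020	168	G	C	29	335	0.766	95.3	15.9	FALSE
G020	138	C	T	54	88	2	70	82	FALSE
G020	289	C	G	18	141	0.829	78.3	90.3	FALSE
G020	381	C	T	24	244	1.098	95.5	63.7	FALSE
G020	366	T	C	10	157	0.348	60.2	68	FALSE
G020	90	G	C	31	133	0.3	76.6	72.5	FALSE
G020	399	A	G	50	210	0.543	89	65.2	FALSE
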