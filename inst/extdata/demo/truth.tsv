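gene_id	position	ref	alt	effect_class	nonsyn	pass
G001	240	C	T	silent	FALSE	TRUE
G001	228	G	C	silent	FALSE	TRUE
G001	92	G	C	nonsynonymous_missense	TRUE	TRUE
G001	109	A	T	nonsynonymous_missense	TRUE	FALSE
G001	222	C	T	silent	FALSE	TRUE
G001	123	G	T	silent	FALSE	FALSE
G001	295	C	T	nonsynonymous_missense	TRUE	TRUE
G002	57	C	A	silent	FALSE	TRUE
G002	6	G	T	silent	FALSE	TRUE
G002	51	C	T	silent	FALSE	TRUE
G002	93	T	C	silent	FALSE	TRUE
G002	24	C	T	silent	FALSE	TRUE
G003	129	G	A	silent	FALSE	TRUE
G003	357	T	C	silent	FALSE	FALSE
G003	171	A	G	silent	FALSE	FALSE
G003	398	T	G	nonsynonymous_missense	TRUE	TRUE
G003	183	C	T	silent	FALSE	TRUE
G003	333	C	T	silent	FALSE	FALSE
G003	48	C	T	silent	FALSE	TRUE
G003	204	A	G	silent	FALSE	FALSE
G004	238	G	T	nonsynonymous_nonsense	TRUE	FALSE
G004	141	G	A	silent	FALSE	FALSE
G004	69	G	T	silent	FALSE	FALSE
G004	24	C	T	silent	FALSE	TRUE
G004	51	G	A	silent	FALSE	FALSE
G005	10	A	C	silent	FALSE	TRUE
G005	48	C	A	nonsynonymous_nonsense	TRUE	TRUE
G005	138	A	T	silent	FALSE	TRUE
G006	24	T	A	silent	FALSE	TRUE
G006	157	G	A	nonsynonymous_missense	TRUE	TRUE
G006	128	T	A	nonsynonymous_missense	TRUE	FALSE
G006	153	C	T	silent	FALSE	TRUE
G006	348	A	T	silent	FALSE	FALSE
G007	126	G	A	silent	FALSE	TRUE
G007	27	G	A	silent	FALSE	FALSE
G007	9	A	G	silent	FALSE	FALSE
G007	39	T	C	silent	FALSE	TRUE
G007	192	G	A	silent	FALSE	TRUE
G008	294	T	C	silent	FALSE	TRUE
G008	57	C	T	silent	FALSE	TRUE
G008	352	A	C	nonsynonymous_missense	TRUE	TRUE
G009	105	C	G	silent	FALSE	TRUE
G009	126	A	G	silent	FALSE	TRUE
G009	174	A	G	silent	FALSE	TRUE
G009	41	T	C	nonsynonymous_missense	TRUE	FALSE
G009	87	G	A	silent	FALSE	FALSE
G009	167	C	T	nonsynonymous_missense	TRUE	FALSE
G009	30	A	G	silent	FALSE	TRUE
G009	36	A	T	silent	FALSE	FALSE
G009	15	G	A	silent	FALSE	TRUE
G010	179	C	G	nonsynonymous_missense	TRUE	TRUE
G010	270	A	G	silent	FALSE	TRUE
G010	153	T	C	silent	FALSE	FALSE
G010	143	C	A	nonsynonymous_missense	TRUE	FALSE
G010	262	G	A	nonsynonymous_missense	TRUE	TRUE
G011	312	T	C	silent	FALSE	TRUE
G011	75	T	C	silent	FALSE	TRUE
G011	54	C	T	silent	FALSE	FALSE
G011	342	T	A	silent	FALSE	FALSE
G011	26	A	G	nonsynonymous_missense	TRUE	FALSE
G012	312	C	T	silent	FALSE	FALSE
G012	195	T	A	silent	FALSE	FALSE
G013	72	C	T	silent	FALSE	FALSE
G013	244	C	A	silent	FALSE	FALSE
G013	102	G	T	nonsynonymous_missense	TRUE	FALSE
G014	286	G	C	nonsynonymous_missense	TRUE	FALSE
G014	384	C	G	nonsynonymous_nonsense	TRUE	FALSE
G014	324	C	A	nonsynonymous_missense	TRUE	FALSE
G014	200	T	C	nonsynonymous_missense	TRUE	TRUE
G014	393	A	C	silent	FALSE	FALSE
G014	366	G	C	silent	FALSE	TRUE
G014	228	G	A	silent	FALSE	FALSE
G014	127	C	T	silent	FALSE	FALSE
G014	255	G	A	silent	FALSE	TRUE
G014	390	A	G	silent	FALSE	TRUE
G014	288	C	T	silent	FALSE	FALSE
G014	46	C	G	nonsynonymous_missense	TRUE	FALSE
G015	201	G	T	silent	FALSE	FALSE
G015	241	C	A	silent	FALSE	FALSE
G015	135	G	A	silent	FALSE	FALSE
G015	84	T	G	silent	FALSE	TRUE
G015	402	T	G	silent	FALSE	FALSE
G015	108	C	T	silent	FALSE	TRUE
G016	270	T	A	silent	FALSE	TRUE
G016	258	T	C	silent	FALSE	FALSE
G017	279	A	T	silent	FALSE	FALSE
G017	306	T	C	silent	FALSE	FALSE
G017	29	T	C	nonsynonymous_missense	TRUE	TRUE
G017	326	A	G	silent	FALSE	FALSE
G017	30	G	C	silent	FALSE	FALSE
G017	229	G	T	nonsynonymous_missense	TRUE	TRUE
G018	6	T	C	silent	FALSE	FALSE
G018	99	G	A	silent	FALSE	FALSE
G018	133	C	G	nonsynonymous_missense	TRUE	FALSE
G018	126	C	T	silent	FALSE	TRUE
G018	81	G	A	silent	FALSE	FALSE
G019	400	C	A	silent	FALSE	FALSE
G019	306	G	A	silent	FALSE	FALSE
G019	66	T	A	silent	FALSE	FALSE
G019	423	A	G	silent	FALSE	FALSE
G020	168	G	C	silent	FALSE	FALSE
G020	138	C	T	silent	FALSE	FALSE
G020	289	C	G	nonsynonymous_missense	TRUE	TRUE
G020	381	C	T	silent	FALSE	TRUE
G020	366	T	C	silent	FALSE	TRUE
G020	90	G	C	silent	FALSE	TRUE
G020	399	A	G	silent	FALSE	TRUE
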