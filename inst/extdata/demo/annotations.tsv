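gene_id	term_id	term_name
G012	T001	synthetic process 1
G020	T001	synthetic process 1
G004	T001	synthetic process 1
G013	T001	synthetic process 1
G002	T001	synthetic process 1
G010	T001	synthetic process 1
G009	T001	synthetic process 1
G005	T001	synthetic process 1
G007	T002	synthetic process 2
G003	T002	synthetic process 2
G005	T002	synthetic process 2
G011	T003	synthetic process 3
G016	T003	synthetic process 3
G006	T003	synthetic process 3
G018	T003	synthetic process 3
G008	T004	synthetic process 4
G006	T004	synthetic process 4
G004	T004	synthetic process 4
G002	T004	synthetic process 4
G009	T004	synthetic process 4
G018	T004	synthetic process 4
G017	T004	synthetic process 4
G010	T004	synthetic process 4
G012	T005	synthetic process 5
G006	T005	synthetic process 5
G003	T005	synthetic process 5
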