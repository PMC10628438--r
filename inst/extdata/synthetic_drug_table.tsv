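# provenance: synthetic snapshot v1 (generated fixture, not a real database export)
drug_id	drug_name	gene_symbol	action	source
D001	compound_001	NETG01		synthetic_v1
D002	compound_002	NETG02	inhibitor	synthetic_v1
D003	compound_003	NETG03		synthetic_v1
D004	compound_004	NETG04	inhibitor	synthetic_v1
D005	compound_005	NETG05		synthetic_v1
D006	compound_006	NETG06	inhibitor	synthetic_v1
D007	compound_007	NETG07		synthetic_v1
D008	compound_008	NETG08	inhibitor	synthetic_v1
D009	compound_009	NETG01		synthetic_v1
D010	compound_010	NETG02	inhibitor	synthetic_v1
D011	compound_011	NETG03		synthetic_v1
D012	compound_012	NETG04	inhibitor	synthetic_v1
D013	compound_013	NETG05		synthetic_v1
D014	compound_014	NETG06	inhibitor	synthetic_v1
D015	compound_015	NETG07		synthetic_v1
D016	compound_016	NETG08	inhibitor	synthetic_v1
D017	compound_017	NETG01		synthetic_v1
D018	compound_018	NETG02	inhibitor	synthetic_v1
D019	compound_019	NETG03		synthetic_v1
D020	compound_020	NETG04	inhibitor	synthetic_v1
D001	compound_001	NETG05		synthetic_v1
D002	compound_002	NETG07	inhibitor	synthetic_v1
D021	compound_021	OFFG01		synthetic_v1
D022	compound_022	OFFG02	agonist	synthetic_v1
D003	compound_003	OFFG03		synthetic_v1
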