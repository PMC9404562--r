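strain_id	human_gut_resident	pathogenic	assembly_available	evidence
synthetic_strain_001	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_002	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_003	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_004	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_005	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_006	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_007	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_008	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_009	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_010	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_011	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_012	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_013	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_014	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_015	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_016	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_017	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_018	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_019	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_020	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_021	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_022	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_023	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_024	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_025	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_026	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_027	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_028	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_029	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_030	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_031	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_032	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_033	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_034	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_035	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_036	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_037	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_038	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_039	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_040	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_041	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_042	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_043	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_044	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_045	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_046	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_047	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_048	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_049	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_050	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_051	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_052	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_053	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_054	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_055	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_056	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_057	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_058	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_059	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_060	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_061	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_062	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_063	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_064	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_065	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_066	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_067	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_068	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_069	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_070	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_071	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_072	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_073	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_074	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_075	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_076	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_077	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_078	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_079	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_080	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_081	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_082	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_083	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_084	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_085	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_086	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_087	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_088	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_089	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_090	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_091	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_092	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_093	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_094	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_095	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_096	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_097	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_098	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_099	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_100	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_101	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_102	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_103	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_104	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_105	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_106	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_107	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_108	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_109	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_110	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_111	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_112	TRUE	FALSE	TRUE	synthetic annotation
synthetic_strain_113	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_114	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_115	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_116	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_117	FALSE	FALSE	TRUE	synthetic annotation
synthetic_strain_118	TRUE	FALSE	FALSE	synthetic annotation
synthetic_strain_119	TRUE	TRUE	TRUE	synthetic annotation
synthetic_strain_120	TRUE	TRUE	TRUE	synthetic annotation
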