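locus_id	ref_len	baseline
MSI_001	8	6:0.018,7:0.063,8:0.91,9:0.009
MSI_002	9	7:0.019,8:0.0665,9:0.905,10:0.0095
MSI_003	10	8:0.02,9:0.07,10:0.9,11:0.01
MSI_004	11	9:0.021,10:0.0735,11:0.895,12:0.0105
MSI_005	12	10:0.022,11:0.077,12:0.89,13:0.011
MSI_006	13	11:0.023,12:0.0805,13:0.885,14:0.0115
MSI_007	14	12:0.024,13:0.084,14:0.88,15:0.012
MSI_008	15	13:0.025,14:0.0875,15:0.875,16:0.0125
MSI_009	8	6:0.018,7:0.063,8:0.91,9:0.009
MSI_010	9	7:0.019,8:0.0665,9:0.905,10:0.0095
MSI_011	10	8:0.02,9:0.07,10:0.9,11:0.01
MSI_012	11	9:0.021,10:0.0735,11:0.895,12:0.0105
MSI_013	12	10:0.022,11:0.077,12:0.89,13:0.011
MSI_014	13	11:0.023,12:0.0805,13:0.885,14:0.0115
MSI_015	14	12:0.024,13:0.084,14:0.88,15:0.012
MSI_016	15	13:0.025,14:0.0875,15:0.875,16:0.0125
MSI_017	8	6:0.018,7:0.063,8:0.91,9:0.009
MSI_018	9	7:0.019,8:0.0665,9:0.905,10:0.0095
MSI_019	10	8:0.02,9:0.07,10:0.9,11:0.01
MSI_020	11	9:0.021,10:0.0735,11:0.895,12:0.0105
MSI_021	12	10:0.022,11:0.077,12:0.89,13:0.011
MSI_022	13	11:0.023,12:0.0805,13:0.885,14:0.0115
MSI_023	14	12:0.024,13:0.084,14:0.88,15:0.012
MSI_024	15	13:0.025,14:0.0875,15:0.875,16:0.0125
MSI_025	8	6:0.018,7:0.063,8:0.91,9:0.009
MSI_026	9	7:0.019,8:0.0665,9:0.905,10:0.0095
MSI_027	10	8:0.02,9:0.07,10:0.9,11:0.01
MSI_028	11	9:0.021,10:0.0735,11:0.895,12:0.0105
MSI_029	12	10:0.022,11:0.077,12:0.89,13:0.011
MSI_030	13	11:0.023,12:0.0805,13:0.885,14:0.0115
MSI_031	14	12:0.024,13:0.084,14:0.88,15:0.012
MSI_032	15	13:0.025,14:0.0875,15:0.875,16:0.0125
MSI_033	8	6:0.018,7:0.063,8:0.91,9:0.009
MSI_034	9	7:0.019,8:0.0665,9:0.905,10:0.0095
MSI_035	10	8:0.02,9:0.07,10:0.9,11:0.01
MSI_036	11	9:0.021,10:0.0735,11:0.895,12:0.0105
MSI_037	12	10:0.022,11:0.077,12:0.89,13:0.011
MSI_038	13	11:0.023,12:0.0805,13:0.885,14:0.0115
MSI_039	14	12:0.024,13:0.084,14:0.88,15:0.012
MSI_040	15	13:0.025,14:0.0875,15:0.875,16:0.0125
MSI_041	8	6:0.018,7:0.063,8:0.91,9:0.009
MSI_042	9	7:0.019,8:0.0665,9:0.905,10:0.0095
MSI_043	10	8:0.02,9:0.07,10:0.9,11:0.01
MSI_044	11	9:0.021,10:0.0735,11:0.895,12:0.0105
MSI_045	12	10:0.022,11:0.077,12:0.89,13:0.011
MSI_046	13	11:0.023,12:0.0805,13:0.885,14:0.0115
MSI_047	14	12:0.024,13:0.084,14:0.88,15:0.012
MSI_048	15	13:0.025,14:0.0875,15:0.875,16:0.0125
MSI_049	8	6:0.018,7:0.063,8:0.91,9:0.009
MSI_050	9	7:0.019,8:0.0665,9:0.905,10:0.0095
MSI_051	10	8:0.02,9:0.07,10:0.9,11:0.01
MSI_052	11	9:0.021,10:0.0735,11:0.895,12:0.0105
MSI_053	12	10:0.022,11:0.077,12:0.89,13:0.011
MSI_054	13	11:0.023,12:0.0805,13:0.885,14:0.0115
MSI_055	14	12:0.024,13:0.084,14:0.88,15:0.012
MSI_056	15	13:0.025,14:0.0875,15:0.875,16:0.0125
MSI_057	8	6:0.018,7:0.063,8:0.91,9:0.009
MSI_058	9	7:0.019,8:0.0665,9:0.905,10:0.0095
MSI_059	10	8:0.02,9:0.07,10:0.9,11:0.01
MSI_060	11	9:0.021,10:0.0735,11:0.895,12:0.0105
MSI_061	12	10:0.022,11:0.077,12:0.89,13:0.011
MSI_062	13	11:0.023,12:0.0805,13:0.885,14:0.0115
MSI_063	14	12:0.024,13:0.084,14:0.88,15:0.012
MSI_064	15	13:0.025,14:0.0875,15:0.875,16:0.0125
MSI_065	8	6:0.018,7:0.063,8:0.91,9:0.009
MSI_066	9	7:0.019,8:0.0665,9:0.905,10:0.0095
MSI_067	10	8:0.02,9:0.07,10:0.9,11:0.01
MSI_068	11	9:0.021,10:0.0735,11:0.895,12:0.0105
MSI_069	12	10:0.022,11:0.077,12:0.89,13:0.011
MSI_070	13	11:0.023,12:0.0805,13:0.885,14:0.0115
MSI_071	14	12:0.024,13:0.084,14:0.88,15:0.012
MSI_072	15	13:0.025,14:0.0875,15:0.875,16:0.0125
MSI_073	8	6:0.018,7:0.063,8:0.91,9:0.009
MSI_074	9	7:0.019,8:0.0665,9:0.905,10:0.0095
MSI_075	10	8:0.02,9:0.07,10:0.9,11:0.01
MSI_076	11	9:0.021,10:0.0735,11:0.895,12:0.0105
MSI_077	12	10:0.022,11:0.077,12:0.89,13:0.011
MSI_078	13	11:0.023,12:0.0805,13:0.885,14:0.0115
MSI_079	14	12:0.024,13:0.084,14:0.88,15:0.012
MSI_080	15	13:0.025,14:0.0875,15:0.875,16:0.0125
MSI_081	8	6:0.018,7:0.063,8:0.91,9:0.009
MSI_082	9	7:0.019,8:0.0665,9:0.905,10:0.0095
MSI_083	10	8:0.02,9:0.07,10:0.9,11:0.01
MSI_084	11	9:0.021,10:0.0735,11:0.895,12:0.0105
MSI_085	12	10:0.022,11:0.077,12:0.89,13:0.011
MSI_086	13	11:0.023,12:0.0805,13:0.885,14:0.0115
MSI_087	14	12:0.024,13:0.084,14:0.88,15:0.012
MSI_088	15	13:0.025,14:0.0875,15:0.875,16:0.0125
MSI_089	8	6:0.018,7:0.063,8:0.91,9:0.009
MSI_090	9	7:0.019,8:0.0665,9:0.905,10:0.0095
MSI_091	10	8:0.02,9:0.07,10:0.9,11:0.01
MSI_092	11	9:0.021,10:0.0735,11:0.895,12:0.0105
MSI_093	12	10:0.022,11:0.077,12:0.89,13:0.011
MSI_094	13	11:0.023,12:0.0805,13:0.885,14:0.0115
MSI_095	14	12:0.024,13:0.084,14:0.88,15:0.012
MSI_096	15	13:0.025,14:0.0875,15:0.875,16:0.0125
MSI_097	8	6:0.018,7:0.063,8:0.91,9:0.009
MSI_098	9	7:0.019,8:0.0665,9:0.905,10:0.0095
MSI_099	10	8:0.02,9:0.07,10:0.9,11:0.01
MSI_100	11	9:0.021,10:0.0735,11:0.895,12:0.0105
MSI_101	12	10:0.022,11:0.077,12:0.89,13:0.011
MSI_102	13	11:0.023,12:0.0805,13:0.885,14:0.0115
MSI_103	14	12:0.024,13:0.084,14:0.88,15:0.012
MSI_104	15	13:0.025,14:0.0875,15:0.875,16:0.0125
MSI_105	8	6:0.018,7:0.063,8:0.91,9:0.009
MSI_106	9	7:0.019,8:0.0665,9:0.905,10:0.0095
MSI_107	10	8:0.02,9:0.07,10:0.9,11:0.01
MSI_108	11	9:0.021,10:0.0735,11:0.895,12:0.0105
MSI_109	12	10:0.022,11:0.077,12:0.89,13:0.011
MSI_110	13	11:0.023,12:0.0805,13:0.885,14:0.0115
MSI_111	14	12:0.024,13:0.084,14:0.88,15:0.012
MSI_112	15	13:0.025,14:0.0875,15:0.875,16:0.0125
MSI_113	8	6:0.018,7:0.063,8:0.91,9:0.009
MSI_114	9	7:0.019,8:0.0665,9:0.905,10:0.0095
MSI_115	10	8:0.02,9:0.07,10:0.9,11:0.01
MSI_116	11	9:0.021,10:0.0735,11:0.895,12:0.0105
MSI_117	12	10:0.022,11:0.077,12:0.89,13:0.011
MSI_118	13	11:0.023,12:0.0805,13:0.885,14:0.0115
MSI_119	14	12:0.024,13:0.084,14:0.88,15:0.012
MSI_120	15	13:0.025,14:0.0875,15:0.875,16:0.0125
MSI_121	8	6:0.018,7:0.063,8:0.91,9:0.009
MSI_122	9	7:0.019,8:0.0665,9:0.905,10:0.0095
MSI_123	10	8:0.02,9:0.07,10:0.9,11:0.01
MSI_124	11	9:0.021,10:0.0735,11:0.895,12:0.0105
MSI_125	12	10:0.022,11:0.077,12:0.89,13:0.011
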