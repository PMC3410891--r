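marker_id	chrom	pos	allele_a	allele_b	line_001	line_002	line_003	line_004	line_005	line_006	line_007	line_008	line_009	line_010	line_011	line_012	line_013	line_014	line_015	line_016	line_017	line_018	line_019	line_020	line_021	line_022	line_023	line_024	line_025	line_026	line_027	line_028	line_029	line_030	line_031	line_032	line_033	line_034	line_035	line_036	line_037	line_038	line_039	line_040	line_041	line_042	line_043	line_044	line_045	line_046	line_047	line_048	line_049	line_050
mk_00001	1	1000	A	B	2	0	0	0	2	2	0	0	2	2	0	0	2	0	2	2	2	2	2	2	2	0	0	2	2	2	2	0	2	0	2	0	0	0	0	2	2	0	0	0	2	0	0	0	0	2	2	0	0	0
mk_00002	1	2000	A	B	2	2	0	0	2	2	0	0	2	2	2	0	0	2	2	2	2	0	2	2	0	2	2	0	2	2	0	0	2	2	0	0	0	2	2	2	0	2	2	0	0	2	0	2	2	2	2	2	0	2
mk_00003	1	3000	A	B	0	2	2	2	2	2	2	2	2	0	0	2	0	2	2	2	2	2	2	0	0	0	0	0	0	2	0	2	0	0	0	2	0	2	0	0	0	2	2	2	2	0	0	0	0	2	0	2	NA	0
mk_00004	1	4000	A	B	0	0	2	2	2	0	0	0	0	2	2	0	2	0	2	0	0	2	0	2	0	0	0	2	0	0	2	0	0	2	0	2	2	0	2	0	2	2	2	0	0	2	2	0	2	2	0	0	2	0
mk_00005	1	5000	A	B	2	0	0	0	2	2	2	0	2	0	0	0	0	0	2	2	0	0	2	2	2	2	0	0	2	2	0	2	2	0	0	2	0	0	0	2	0	2	0	2	0	2	0	0	0	0	2	0	2	2
mk_00006	1	6000	A	B	0	0	0	0	2	0	0	0	2	0	0	0	2	2	2	0	2	2	2	2	2	2	2	0	2	0	0	2	0	0	0	0	0	2	0	0	0	2	2	0	2	0	0	0	0	2	2	0	0	2
mk_00007	1	7000	A	B	0	2	0	2	2	2	2	0	2	2	2	0	0	2	0	2	0	0	2	2	2	2	0	0	2	0	0	0	0	0	NA	0	2	0	2	2	2	0	0	0	0	2	2	0	0	2	0	0	0	0
mk_00008	1	8000	A	B	2	0	0	0	0	0	2	0	2	0	2	2	0	0	2	2	0	2	2	2	2	2	0	2	0	0	0	0	0	0	2	0	2	2	2	0	2	2	2	2	0	2	0	2	0	0	2	0	0	2
mk_00009	1	9000	A	B	0	2	0	0	0	2	2	0	0	2	0	0	2	0	0	2	2	2	0	2	0	0	0	2	2	0	2	2	2	2	2	2	0	2	0	2	0	0	0	0	2	0	0	2	2	0	2	2	0	2
mk_00010	1	10000	A	B	2	2	0	0	0	2	2	2	2	0	2	2	0	0	0	0	0	2	2	0	0	0	2	2	0	2	2	2	2	0	2	0	2	2	0	0	0	2	2	0	0	0	0	2	0	0	2	2	2	2
mk_00011	1	11000	A	B	0	2	0	0	2	2	2	2	0	2	0	2	2	0	2	2	2	0	0	2	0	0	2	0	0	0	0	0	2	0	2	0	2	2	2	0	0	0	0	2	0	2	0	2	0	0	2	0	2	0
mk_00012	1	12000	A	B	2	0	2	0	0	2	2	0	2	0	2	2	0	0	0	0	2	2	2	0	2	NA	0	2	0	2	0	2	0	2	2	2	0	0	0	0	2	0	0	2	2	0	2	0	0	2	2	2	2	2
mk_00013	1	13000	A	B	0	2	0	0	0	0	2	2	2	2	0	0	0	2	0	2	2	0	2	2	0	0	2	2	0	2	2	2	2	2	0	0	2	0	2	2	0	2	2	2	2	2	2	2	0	0	0	2	2	0
mk_00014	1	14000	A	B	2	2	NA	2	2	2	0	0	2	0	2	0	0	0	0	0	2	0	2	0	0	0	0	0	2	0	2	0	2	0	0	2	2	0	2	2	2	2	2	0	0	2	0	2	0	0	0	2	2	0
mk_00015	1	15000	A	B	0	0	2	0	0	0	2	2	0	0	2	0	2	0	0	2	2	2	0	2	0	2	0	2	NA	2	2	0	0	2	2	2	0	2	2	2	2	2	2	2	2	2	2	0	2	2	0	0	2	0
mk_00016	1	16000	A	B	0	2	0	0	0	2	0	0	0	0	2	2	2	2	2	2	0	2	0	2	0	2	2	2	0	0	0	0	0	2	0	2	0	0	0	2	2	2	0	0	0	0	2	2	2	2	0	0	2	2
mk_00017	1	17000	A	B	2	2	0	0	2	0	2	2	2	0	2	2	2	2	2	2	0	0	2	2	0	2	0	2	2	2	0	0	0	2	0	0	2	2	0	0	2	0	2	2	0	0	0	2	2	0	2	2	2	2
mk_00018	1	18000	A	B	0	2	2	2	2	0	0	0	2	2	2	2	0	2	2	0	2	0	0	0	2	0	2	2	2	2	2	2	2	2	0	0	0	0	2	2	0	2	0	2	2	2	0	2	2	0	0	2	2	2
mk_00019	1	19000	A	B	0	0	2	2	2	2	0	2	0	0	2	2	2	0	0	2	0	0	0	2	2	0	0	0	0	2	0	0	0	0	0	2	0	2	2	0	0	2	2	2	0	2	0	2	0	2	0	0	2	0
mk_00020	1	20000	A	B	0	2	0	0	2	2	0	0	2	0	0	2	2	0	2	0	0	0	2	0	0	0	2	0	2	0	2	2	0	2	2	0	0	2	2	2	2	0	0	2	0	2	2	0	NA	0	0	2	0	2
mk_00021	1	21000	A	B	0	0	2	2	0	2	2	2	0	2	0	2	2	2	0	2	2	0	2	0	2	2	0	2	0	2	0	2	2	2	2	0	2	2	0	2	0	0	2	0	2	2	2	0	0	0	0	2	2	2
mk_00022	1	22000	A	B	0	2	0	2	2	0	2	0	2	2	2	0	0	0	0	2	0	0	0	2	0	2	0	2	0	0	2	2	NA	2	0	2	2	0	2	2	0	0	0	2	0	2	2	0	0	0	0	2	0	0
mk_00023	1	23000	A	B	0	2	2	0	2	0	0	0	2	2	0	2	2	2	2	2	2	2	2	2	0	0	0	0	2	0	2	0	2	2	0	0	0	2	2	2	2	2	0	0	0	0	2	0	0	0	2	0	0	0
mk_00024	1	24000	A	B	0	2	2	2	0	2	2	0	0	0	2	0	0	2	0	2	0	0	0	2	0	0	0	0	0	2	2	2	2	2	2	0	0	2	0	0	2	0	0	0	2	0	2	2	0	0	2	0	2	NA
mk_00025	1	25000	A	B	0	0	2	0	2	0	2	0	0	0	2	2	2	0	2	2	0	0	2	2	2	2	0	2	2	2	0	0	0	2	2	0	0	2	2	0	0	2	2	2	2	2	0	2	2	0	2	2	0	0
mk_00026	1	26000	A	B	0	2	0	2	0	2	2	2	0	0	0	0	2	2	2	2	0	NA	0	2	0	2	2	0	0	2	2	2	0	2	2	0	0	0	2	2	0	0	2	2	2	2	0	0	0	0	0	2	0	0
mk_00027	1	27000	A	B	0	2	0	NA	0	2	2	0	0	2	2	0	0	0	2	2	2	0	0	2	0	0	0	2	2	0	2	2	0	0	2	0	2	0	0	2	0	2	2	0	2	0	0	2	2	0	2	2	0	2
mk_00028	1	28000	A	B	0	2	2	2	NA	2	0	2	2	2	2	0	2	2	0	2	2	0	2	0	2	2	0	0	0	2	0	2	0	2	0	2	0	0	0	2	0	2	0	0	0	0	0	2	2	0	2	0	0	0
mk_00029	1	29000	A	B	0	0	2	2	2	0	0	0	2	2	0	0	2	0	2	2	0	0	0	2	0	0	0	2	2	2	0	0	0	0	0	0	2	2	2	0	2	0	2	2	2	0	0	0	2	2	2	0	0	0
mk_00030	1	30000	A	B	2	0	0	2	2	2	2	0	2	0	2	0	2	2	2	0	0	2	0	2	0	2	0	0	2	2	0	0	2	2	2	2	0	2	2	2	2	0	2	2	2	2	0	0	0	0	2	0	2	0
mk_00031	1	31000	A	B	2	2	0	2	0	0	2	2	0	NA	0	2	0	0	0	2	0	2	2	2	0	0	2	2	0	2	0	2	2	2	0	2	2	0	0	0	2	2	0	2	0	2	0	2	2	0	2	0	2	2
mk_00032	1	32000	A	B	0	2	0	0	0	2	2	2	2	2	0	0	0	2	2	2	2	2	2	2	2	2	2	2	0	0	2	2	2	2	2	2	0	2	2	2	2	0	2	2	0	2	2	2	0	2	2	2	2	2
mk_00033	1	33000	A	B	2	2	2	0	0	2	0	0	0	0	0	2	2	2	2	0	2	0	0	0	2	0	0	2	0	2	0	2	0	0	0	0	2	2	0	2	2	2	2	2	0	2	0	0	2	2	2	0	0	0
mk_00034	1	34000	A	B	0	0	2	0	0	2	0	2	0	0	2	0	2	2	0	0	0	0	2	2	2	0	2	2	0	2	0	0	2	0	2	2	0	0	0	2	2	2	0	0	2	2	2	2	0	0	0	2	0	2
mk_00035	1	35000	A	B	2	0	2	2	2	0	0	0	2	0	0	2	0	2	0	0	0	2	0	2	0	0	2	2	2	0	2	0	2	2	0	2	0	2	2	0	2	2	0	2	0	2	0	0	0	0	0	0	0	2
mk_00036	1	36000	A	B	0	0	2	2	2	2	2	NA	0	0	NA	2	2	2	2	2	0	0	2	0	0	2	0	NA	0	0	2	0	2	0	0	2	0	2	2	0	2	0	2	2	0	2	0	2	0	0	0	2	2	0
mk_00037	1	37000	A	B	0	2	0	0	2	0	0	2	0	2	2	0	0	2	0	2	0	0	0	0	2	0	0	0	0	2	2	0	2	0	0	0	0	0	2	2	0	2	0	2	0	2	2	2	2	0	0	0	0	2
mk_00038	1	38000	A	B	0	0	2	0	2	2	2	2	2	0	2	0	0	0	2	2	2	0	0	0	2	0	0	2	0	0	0	2	0	2	0	2	2	0	0	0	NA	2	0	0	0	2	2	2	NA	0	0	0	0	0
mk_00039	1	39000	A	B	2	2	2	0	2	0	2	2	0	0	2	2	2	0	2	2	0	2	2	0	2	0	2	0	2	2	2	2	0	2	2	0	0	2	2	2	2	2	2	2	0	2	0	0	0	2	2	2	2	2
mk_00040	1	40000	A	B	0	0	0	0	0	2	0	2	2	2	2	0	0	2	0	0	0	2	0	0	0	0	0	0	0	2	2	2	0	0	0	0	2	2	2	2	2	0	0	2	2	0	2	2	0	0	0	2	0	2
mk_00041	1	41000	A	B	0	0	0	0	2	0	0	0	2	2	2	2	2	2	2	0	2	2	0	0	2	2	2	2	2	2	0	0	0	2	0	0	2	2	0	2	2	0	0	0	2	0	0	0	0	2	2	0	2	2
mk_00042	1	42000	A	B	2	2	2	2	NA	2	0	NA	2	2	2	0	0	0	2	2	2	0	0	2	2	0	2	0	0	0	2	0	0	0	0	2	2	0	0	0	0	0	2	2	0	2	0	0	0	2	0	0	0	0
mk_00043	1	43000	A	B	0	0	2	0	2	0	2	2	2	0	2	0	2	0	2	0	2	0	2	2	0	2	0	2	2	0	0	2	2	2	0	0	0	2	2	0	2	NA	0	0	2	0	0	0	2	0	0	0	0	2
mk_00044	1	44000	A	B	0	0	0	2	2	0	0	0	2	0	2	0	2	0	0	2	0	0	2	0	0	2	2	0	2	2	0	2	2	2	0	2	0	0	0	2	2	0	2	2	0	2	2	0	2	2	0	2	0	2
mk_00045	1	45000	A	B	0	0	0	0	2	2	0	2	0	2	0	2	0	2	0	0	0	2	0	2	0	2	0	2	0	0	0	0	2	2	0	2	0	0	2	2	0	2	2	2	0	0	0	2	0	2	0	2	0	2
mk_00046	1	46000	A	B	0	0	0	2	2	0	0	0	2	0	2	0	0	2	0	2	2	0	2	0	0	2	0	0	2	0	2	2	2	2	2	2	0	2	0	0	2	NA	2	2	0	0	2	2	0	0	0	0	2	0
mk_00047	1	47000	A	B	2	2	0	2	0	0	0	2	0	2	2	0	2	2	0	NA	2	0	0	2	2	0	0	2	0	2	0	0	0	0	2	2	2	0	0	2	0	0	0	2	2	2	0	2	2	0	2	2	2	0
mk_00048	1	48000	A	B	0	2	0	0	0	0	0	0	0	2	2	2	2	0	0	0	0	0	2	0	0	0	0	2	2	0	0	0	0	2	2	2	0	0	2	2	2	2	2	2	2	0	0	2	2	2	2	2	2	2
mk_00049	1	49000	A	B	2	0	0	0	2	2	0	0	0	2	2	0	0	2	2	0	0	2	0	0	2	2	2	0	2	0	2	0	2	2	2	0	0	0	0	2	0	0	2	2	2	0	0	0	0	2	2	0	2	2
mk_00050	1	50000	A	B	0	2	0	0	2	0	2	2	0	2	0	0	0	0	0	0	0	0	2	0	0	2	2	2	0	0	0	0	0	2	0	2	0	2	0	0	0	0	0	2	2	2	0	2	2	2	0	2	2	2
mk_00051	1	51000	A	B	2	0	2	0	0	2	2	2	0	2	2	0	0	0	0	2	0	2	2	0	2	2	2	2	NA	2	0	0	2	2	0	0	0	0	0	0	2	0	0	2	0	2	2	0	0	0	0	0	2	2
mk_00052	1	52000	A	B	2	2	2	0	2	2	0	0	0	0	2	2	2	0	0	0	2	2	2	2	0	2	2	2	0	2	0	0	0	2	2	0	0	0	2	2	2	0	0	0	0	0	2	0	2	0	2	2	2	2
mk_00053	1	53000	A	B	2	0	0	0	2	0	0	0	2	0	2	2	2	2	2	2	2	2	0	0	0	0	0	0	0	0	2	0	0	0	2	0	2	2	0	0	0	2	0	2	2	2	0	0	2	2	0	0	2	2
mk_00054	1	54000	A	B	2	0	2	0	2	0	2	0	0	0	0	0	0	2	0	0	2	2	0	0	2	0	2	2	0	0	2	0	0	0	2	2	2	NA	2	2	0	0	2	2	2	2	0	2	0	NA	2	2	0	2
mk_00055	1	55000	A	B	2	0	0	2	2	2	0	2	2	0	0	0	2	2	2	2	0	2	2	0	2	2	0	2	0	2	2	0	2	0	2	NA	0	0	0	0	2	2	0	0	0	0	2	2	2	0	0	0	0	0
mk_00056	1	56000	A	B	2	0	2	2	2	2	0	NA	0	0	0	2	0	2	2	0	2	0	0	0	0	0	0	2	NA	2	0	0	2	0	0	2	0	0	2	0	NA	0	0	2	0	2	0	2	2	0	0	0	2	2
mk_00057	1	57000	A	B	2	2	2	2	2	2	0	2	2	0	2	0	0	2	2	0	2	0	2	0	2	2	0	0	0	0	2	0	2	0	2	0	2	0	2	2	0	0	0	2	0	0	0	2	0	2	2	2	2	2
mk_00058	1	58000	A	B	0	0	2	0	2	0	0	0	0	2	2	0	2	2	0	2	2	2	0	2	0	2	2	0	2	2	2	0	2	0	0	2	0	0	2	0	2	0	2	2	2	2	2	0	0	2	0	0	0	0
mk_00059	1	59000	A	B	2	0	2	0	0	0	2	2	0	0	2	0	2	0	0	0	2	2	2	0	0	0	2	2	2	0	2	2	2	0	2	2	0	0	2	2	2	0	2	2	0	0	2	0	0	0	0	2	2	0
mk_00060	1	60000	A	B	0	2	2	2	0	2	0	2	0	2	2	2	2	2	NA	0	0	2	0	0	2	2	0	2	2	0	2	0	2	2	2	0	2	0	0	0	0	0	0	2	0	2	2	2	2	2	2	2	0	0
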