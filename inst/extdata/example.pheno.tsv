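accession_id	trait_a	trait_b
line_001	-4.07941639814638	7.2240075668143
line_002	-0.478593018084904	12.5458337285105
line_003	-1.00797653829218	NA
line_004	0.0520396021905641	11.5045597914801
line_005	1.28357760937932	11.1834901049255
line_006	0.550070141100203	8.03389480845796
line_007	-0.00586798912625335	9.44787208977599
line_008	0.688628623177395	8.25829795486282
line_009	-0.905026795024674	11.4374211061685
line_010	-6.44056491009204	10.2213057555387
line_011	1.1263644461094	NA
line_012	-0.114954297305509	9.159019081316
line_013	2.14289420130839	8.87574824742947
line_014	0.540240403230885	11.9950268895106
line_015	-0.0539137798983924	7.78973988237347
line_016	1.96021323687189	9.71542433845083
line_017	-2.914830374582	10.6299898097758
line_018	1.50823281874887	12.4371010690147
line_019	3.47613995462638	8.60136584262897
line_020	4.1272957674574	9.42913449694255
line_021	-0.881376116074713	7.37689465478123
line_022	-0.293608815969603	9.21797513710148
line_023	1.06797708699898	9.19694677381005
line_024	-1.05577218743858	12.7010351618459
line_025	1.66203430332658	11.1823800541784
line_026	-0.293452445213182	10.2010509112571
line_027	-1.40946025523161	11.8621439910402
line_028	0.0581583545777107	9.47451530286694
line_029	-0.0807050803918838	9.98466379057467
line_030	-0.416917760011038	10.7343060130913
line_031	-1.16631706961735	13.4143250902752
line_032	0.701624525147443	11.4474805250568
line_033	1.78087238407548	10.9620720974158
line_034	-0.394032967667513	6.8642635115495
line_035	-1.18521985244683	10.6365005669617
line_036	-1.95597638607212	10.3319829013547
line_037	0.793757493744607	8.20018474074366
line_038	0.0157172082410916	10.1527429477211
line_039	-1.0817580750637	10.3183105565255
line_040	0.226529792263782	11.0873483694194
line_041	0.0501629832875919	11.4096147052261
line_042	0.313337526654623	10.6379382851142
line_043	-0.112203092223847	12.2184995779421
line_044	-1.46346762563705	11.5383083893142
line_045	1.37975694191762	12.3069473495579
line_046	3.72001634369607	12.5213670053619
line_047	0.403687298046476	11.4012470131446
line_048	1.55317496806462	10.8652543216919
line_049	0.918728858306006	8.15479656348616
line_050	-0.999532883153992	8.76883158673816
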