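compound	rt_library_min	rt_observed_min	delta_min	calc_mz	meas_mz	ppm_reported	match_score
Cucumarioside H8	6.3	6.3	0.0	1281.5216	1281.5135	6.3	0.930
Cucumarioside I3	6.7	6.6	0.1	702.2487	702.2474	1.7	0.752
Cucumarioside I4	7.4	7.4	0.0	630.2093	630.2104	-1.7	0.777
Cucumarioside H2	7.7	7.6	0.1	1325.5478	1325.5474	0.3	0.905
Colochiroside B1	8.1	8.1	0.0	1193.5055	1193.4989	5.6	0.801
Pacificusoside A	8.1	8.2	0.1	1201.5284	1201.5260	2.0	0.911
Colochiroside B2	8.3	8.3	0.0	1193.5055	1193.5030	2.1	0.936
Cucumarioside H3	8.8	8.8	0.0	1181.4691	1181.4680	1.0	0.954
Quadrangularisoside A	9.0	9.0	0.0	1209.5004	1209.4946	4.8	0.907
Cucumarioside A7	9.7	9.8	0.1	1113.5487	1113.5455	2.9	0.826
Cucumarioside A11	10.0	10.0	0.0	1113.5487	1113.5454	3.0	0.917
Pacificusoside J	10.1	10.1	0.0	1131.5229	1131.5194	3.1	0.951
Pacificusoside B	10.5	10.6	0.1	1101.5123	1101.5099	2.2	0.947
Magnumoside B3	10.6	10.8	0.2	1135.5000	1135.4929	6.3	0.889
Cucumarioside H4	11.7	11.5	0.2	1353.5791	1353.5759	2.3	0.941
Typicoside C2	12.0	12.0	0.0	643.2354	643.2363	-1.5	0.887
Cucumarioside H5	12.4	12.6	0.2	1307.5372	1307.5366	0.5	0.916
Colochiroside A1	13.2	12.9	0.3	1193.5051	1193.5055	-0.3	0.825
Cucumarioside H6	13.6	13.4	0.2	1309.5529	1309.5569	-3.1	0.892
Typicoside A1	13.7	13.7	0.0	1175.4950	1175.4933	1.4	0.800
Cucumarioside D	14.2	14.3	0.1	1257.5910	1257.5961	-4.1	0.763
Pacificusoside G	14.5	14.6	0.1	1081.5225	1081.5248	-2.1	0.820
Cucumarioside C1	14.7	14.8	0.1	1227.5804	1227.5812	-0.6	0.944
Pacificusoside E	14.9	15.0	0.1	1081.5225	1081.5195	2.7	0.975
Cucumarioside C2	15.1	15.2	0.1	1227.5804	1227.5812	-0.6	0.976
Cucumarioside A1	17.1	17.2	0.1	1097.5538	1097.5474	5.9	0.860
Cucumarioside A15	18.7	18.7	0.0	1099.5694	1099.5643	4.7	0.970
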