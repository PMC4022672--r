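!Series_title	"Synthetic knockout vs wild-type example (generated by cvdelta::simulate_dataset, f_cv = 1.4, seed 2026)"
!Sample_title	"wild type replicate 1"	"wild type replicate 2"	"wild type replicate 3"	"wild type replicate 4"	"knockout replicate 1"	"knockout replicate 2"	"knockout replicate 3"	"knockout replicate 4"
!Sample_geo_accession	"GSM90001"	"GSM90002"	"GSM90003"	"GSM90004"	"GSM90005"	"GSM90006"	"GSM90007"	"GSM90008"
!Sample_characteristics_ch1	"genotype: WT"	"genotype: WT"	"genotype: WT"	"genotype: WT"	"genotype: KO"	"genotype: KO"	"genotype: KO"	"genotype: KO"
!series_matrix_table_begin
"ID_REF"	"GSM90001"	"GSM90002"	"GSM90003"	"GSM90004"	"GSM90005"	"GSM90006"	"GSM90007"	"GSM90008"
"1400001_at"	256.9102	312.8746	242.5467	269.0507	279.0816	296.9786	226.6344	297.0111
"1400002_at"	13.5482	12.4011	15.8807	16.1493	14.4328	11.9372	11.9266	9.9251
"1400003_at"	124.9527	128.0476	135.5014	144.3448	141.1639	132.1937	127.6409	150.1458
"1400004_at"	84.9714	90.6371	91.6564	89.8903	89.0206	89.6496	77.3221	92.7993
"1400005_at"	22.5301	26.3393	29.7502	32.9823	25.0567	27.8905	29.1921	31.6867
"1400006_at"	0.0010	2.8061	3.2336	4.3375	0.0010	2.7403	2.9875	1.2833
"1400007_at"	19.4360	22.7256	28.1671	28.2878	28.9195	23.8629	26.7456	29.9467
"1400008_at"	20.3508	15.1122	12.8264	15.2670	17.8386	13.8712	16.0031	13.3628
"1400009_at"	112.0124	131.3191	129.0232	136.1133	125.4460	104.3942	110.7343	126.7943
"1400010_at"	43.6019	47.0673	37.7687	35.4668	32.2215	45.3309	32.6203	39.3415
"1400011_at"	45.6537	47.9904	48.9021	49.9958	46.9847	55.3365	33.2524	49.1978
"1400012_at"	25.2947	33.3070	26.4998	28.4314	28.9816	23.2151	22.6259	24.7744
"1400013_at"	77.7783	71.0747	85.2350	62.2016	68.5659	80.5187	61.3592	73.8193
"1400014_at"	63.1614	61.7545	68.3214	68.3360	66.7677	62.1756	70.1108	82.1059
"1400015_at"	0.0010	5.1872	2.7385	0.0010	0.2406	0.0010	0.0010	3.4024
"1400016_at"	1074.1374	1183.2855	1387.6023	1118.8428	1436.2592	945.8887	1272.4369	1001.8420
"1400017_at"	374.6528	278.2130	297.1249	305.0884	271.2238	311.9361	241.4167	253.2699
"1400018_at"	156.8181	154.0878	122.1333	168.9159	132.6999	131.0553	182.8661	173.2646
"1400019_at"	23.4054	24.1357	16.9328	20.9277	26.1795	24.6893	18.6061	19.8445
"1400020_at"	385.1687	371.4358	360.5856	334.4352	448.1758	357.4976	380.8320	373.6668
"1400021_at"	51.8294	56.9048	53.6218	58.3391	49.2885	58.6793	67.6223	60.5858
"1400022_at"	85.3646	75.5184	78.3718	79.0214	83.9157	72.8975	65.7501	80.6835
"1400023_at"	6.1193	5.7384	6.4528	6.6190	3.2422	6.4638	6.9189	6.5519
"1400024_at"	1259.7363	1298.1854	1209.2788	1470.2591	1396.8309	1569.0630	1347.7892	1420.0405
"1400025_at"	110.2339	120.9224	106.9797	107.8441	108.9406	117.5072	112.6125	112.9414
"1400026_at"	3647.8102	3052.1181	3952.6641	3036.3229	3669.4602	3966.7162	3619.4039	2988.0887
"1400027_at"	2424.6981	2507.7332	2322.7231	2430.1331	2325.2250	2366.1393	1909.1936	2349.4275
"1400028_at"	102.4145	119.9727	104.9077	128.8450	122.8397	119.1113	96.3731	99.6918
"1400029_at"	367.6217	334.6111	324.9673	357.4884	333.6174	351.4825	264.5781	278.6331
"1400030_at"	2983.6386	2027.5437	2795.4566	2228.1752	2466.8512	2242.1284	2551.2634	2452.6319
"1400031_at"	26.4457	34.1165	35.4913	39.4776	47.4598	28.8256	34.7181	38.0697
"1400032_at"	155.9191	144.5713	148.7444	135.7581	123.9038	122.1444	124.0961	137.9050
"1400033_at"	57.8368	64.0160	59.3342	60.3391	80.6557	60.9294	57.0674	62.2872
"1400034_at"	200.9078	194.4886	178.6614	200.0840	211.9615	187.1885	138.7112	181.8057
"1400035_at"	112.8589	147.5597	138.1014	151.0939	177.6145	114.1770	153.7234	137.1490
"1400036_at"	832.8826	949.7005	922.5899	931.2401	888.7589	841.4110	761.7603	671.0325
"1400037_at"	269.7505	277.9477	317.8281	309.2470	309.6443	251.7636	327.3161	347.1595
"1400038_at"	16.1604	17.3348	23.5591	19.0844	18.2284	22.0522	24.8468	24.5508
"1400039_at"	259.5773	292.4124	321.1453	274.3882	314.3379	295.4146	343.7157	326.6489
"1400040_at"	23.6622	20.4167	32.8981	17.2688	22.0198	15.8541	24.8326	30.2193
"1400041_at"	14.2537	16.2041	12.6465	10.7438	17.9060	13.2412	13.4982	16.9582
"1400042_at"	399.2005	384.0137	315.0540	477.7581	470.6352	370.9877	376.0248	398.0093
"1400043_at"	13.0674	7.8159	12.1238	7.7380	10.2026	13.5712	9.2048	14.9002
"1400044_at"	155.0378	189.1859	163.7259	177.2592	196.1381	151.7599	179.0827	161.3397
"1400045_at"	22.4779	18.8477	23.0052	21.0639	28.0719	15.8183	21.9132	26.6261
"1400046_at"	1441.1056	1329.7273	1520.6931	1334.0577	1416.5887	1191.5608	1366.5091	1437.2038
"1400047_at"	314.2084	397.3228	346.0665	339.0696	345.1444	349.7463	384.2654	373.4024
"1400048_at"	56.9174	47.8533	42.2028	43.7141	49.2862	46.8901	53.3937	46.2665
"1400049_at"	385.0028	404.6988	462.1664	490.8057	418.7397	385.1887	305.5455	453.0012
"1400050_at"	197.5067	210.8974	238.5899	218.4352	200.3784	210.2394	207.7725	242.7408
"1400051_at"	12.1311	12.1617	11.0891	13.7674	10.5301	15.2860	12.0166	16.2831
"1400052_at"	58.8239	61.7257	66.1931	60.2182	75.5432	71.6997	68.6185	57.0167
"1400053_at"	20.9082	20.7817	17.3879	23.0783	19.8933	19.6871	18.3763	13.3942
"1400054_at"	239.5654	219.5602	234.2355	241.0160	239.5755	199.1882	288.7840	279.1520
"1400055_at"	25.0537	31.0768	25.3936	31.0233	25.2585	37.5009	29.6647	29.1924
"1400056_at"	63.7450	66.0483	72.0164	75.6693	55.7888	80.9839	65.6772	76.5444
"1400057_at"	10.3740	10.5008	8.1782	10.6890	2.7394	5.3837	5.9667	9.1362
"1400058_at"	17.6585	19.7623	20.9534	21.5347	16.2793	17.7615	23.2507	19.7935
"1400059_at"	155.2468	148.0489	130.5021	126.8477	102.4169	143.4631	116.3330	111.1824
"1400060_at"	12.8368	15.6057	17.1260	16.4219	17.1600	12.1261	22.4479	9.2381
!series_matrix_table_end
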