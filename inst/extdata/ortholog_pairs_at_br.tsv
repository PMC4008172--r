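ref_gene	ref_type	ref_location	ref_orf_length	ref_exons	counterpart	counterpart_type	counterpart_location	counterpart_orf_length	counterpart_exons
AT1G50180.1	NBS	Chr1	2901	5	Bra014241	CC-NBS	A08	4047	3
AT1G58410.1	NBS	Chr1	3070	3	Bra027866	CC-NBS	A09	2986	3
AT1G59620.1	NBS	Chr1	3401	5	Bra035424	CC-NBS	NY	3017	3
AT1G59620.1	NBS	Chr1	3401	5	Bra016781	CC-NBS-LRR	A08	2662	2
AT1G12290.1	CC-NBS-LRR	Chr1	2888	1	Bra026979	CC-NBS-LRR	A09	2744	1
AT4G26090.1	CC-NBS-LRR	Chr4	3534	1	Bra013947	CC-NBS-LRR	A01	2723	1
AT4G26090.1	CC-NBS-LRR	Chr4	3534	1	Bra019063	CC-NBS-LRR	A03	3029	1
AT4G26090.1	CC-NBS-LRR	Chr4	3534	1	Bra037139	CC-NBS-LRR	A09	3023	4
AT3G51560.1	TIR-NBS-LRR	Chr3	4105	5	Bra036791	TIR-NBS-LRR	A09	10379	6
AT1G17610.1	NBS	Chr1	1462	1	Bra030997	NBS	A09	1262	1
AT1G52660.1	NBS	Chr1	1321	3	Bra018980	NBS	A06	1308	3
AT3G15700.1	NBS	Chr3	1240	2	Bra021130	NBS	A01	1322	2
AT3G46710.1	NBS	Chr3	2543	1	Bra018198	NBS	A06	2078	5
AT4G19060.1	NBS	Chr4	1384	1	Bra013373	NBS	A01	716	1
AT5G11250.1	TIR-NBS-LRR	Chr5	3982	4	Bra008977	NBS	A10	518	1
AT5G45490.1	NBS	Chr5	1394	1	Bra021980	NBS	A02	1130	1
AT5G56220.1	NBS	Chr5	3102	1	Bra002834	NBS	A10	2918	1
AT1G12210.1	NBS-LRR	Chr1	2657	1	Bra019755	NBS-LRR	A06	2682	2
AT1G12220.1	NBS-LRR	Chr1	2882	1	Bra019754	NBS-LRR	A06	2672	1
AT1G12220.1	NBS-LRR	Chr1	2882	1	Bra016311	NBS-LRR	A08	4678	5
AT3G14460.1	NBS-LRR	Chr3	4274	1	Bra027333	NBS-LRR	A05	4229	1
AT3G14470.1	NBS-LRR	Chr3	3307	1	Bra027332	NBS-LRR	A05	3128	1
AT4G12020.2	NBS-LRR	Chr4	7992	16	Bra000758	NBS-LRR	A03	4423	5
AT4G19050.1	NBS-LRR	Chr4	3684	2	Bra013372	NBS-LRR	A01	3541	2
AT4G27190.1	CC-NBS-LRR	Chr4	2957	1	Bra026368	NBS-LRR	A01	2933	1
AT4G33300.1	NBS-LRR	Chr4	5475	5	Bra034556	NBS-LRR	A08	3140	5
AT5G04720.1	NBS	Chr5	3172	5	Bra009434	NBS-LRR	A10	3120	5
AT5G04720.1	NBS	Chr5	3172	5	Bra022036	NBS-LRR	A02	6957	6
AT5G66900.1	CC-NBS-LRR	Chr5	3024	5	Bra012116	NBS-LRR	A07	4738	7
AT1G61310.1	CC-NBS-LRR	Chr1	2880	1	Bra027097	NBS-NBS-LRR	A09	2736	3
AT1G17615.1	TIR-NBS	Chr1	1226	2	Bra025962	TIR-NBS	A06	1634	2
AT1G72840.1	TIR-NBS-LRR	Chr1	4529	4	Bra008053	TIR-NBS	A02	8376	5
AT1G72860.1	TIR-NBS	Chr1	4550	3	Bra008056	TIR-NBS	A02	1832	2
AT1G72890.1	TIR-NBS	Chr1	1770	2	Bra016029	TIR-NBS	A07	1428	2
AT1G72890.1	TIR-NBS	Chr1	1770	2	Bra008060	TIR-NBS	A02	1685	2
AT1G72890.1	TIR-NBS	Chr1	1770	2	Bra003864	TIR-NBS	A07	1661	2
AT1G72950.1	TIR-NBS	Chr1	1395	2	Bra016028	TIR-NBS	A07	1366	2
AT5G45240.1	TIR-NBS-LRR	Chr5	5383	10	Bra021957	TIR-NBS	A02	7454	2
AT1G27170.1	TIR-NBS-LRR	Chr1	4858	5	Bra024651	TIR-NBS-LRR	A09	3671	4
AT1G27180.1	TIR-TIR-NBS	Chr1	6247	6	Bra016314	TIR-NBS-LRR	A08	4645	5
AT1G63730.1	TIR-NBS-LRR	Chr1	3362	4	Bra027791	TIR-NBS-LRR	A09	13529	6
AT1G63730.1	TIR-NBS-LRR	Chr1	3362	4	Bra003867	TIR-NBS-LRR	A07	6912	10
AT3G51570.1	TIR-NBS-LRR	Chr3	4098	5	Bra036790	TIR-NBS-LRR	A09	4182	6
AT4G12010.1	TIR-NBS-LRR	Chr4	4182	5	Bra029431	TIR-NBS-LRR	A09	4646	5
AT4G12010.1	TIR-NBS-LRR	Chr4	4182	5	Bra000759	TIR-NBS-LRR	A03	3934	5
AT4G16890.1	TIR-NBS-LRR	Chr4	4949	7	Bra012688	TIR-NBS-LRR	A03	5918	9
AT4G19500.1	TIR-NBS-TIR-NBS-LRR	Chr4	4736	5	Bra013400	TIR-NBS-LRR	A01	5825	8
AT4G19500.1	TIR-NBS-TIR-NBS-LRR	Chr4	4736	5	Bra012540	TIR-NBS-LRR	A03	4567	8
AT4G36150.1	TIR-NBS-LRR	Chr4	3992	5	Bra011666	TIR-NBS-LRR	A01	4726	6
AT5G17680.1	TIR-NBS-LRR	Chr5	4154	4	Bra013959	TIR-NBS-LRR	A08	4066	4
AT5G17970.1	TIR-NBS-LRR	Chr5	2620	4	Bra002117	TIR-NBS-LRR	A10	3627	4
AT5G17970.1	TIR-NBS-LRR	Chr5	2620	4	Bra023647	TIR-NBS-LRR	A02	2888	4
AT5G18350.1	TIR-NBS-LRR	Chr5	4500	6	Bra002154	TIR-NBS-LRR	A10	4737	5
AT5G18350.1	TIR-NBS-LRR	Chr5	4500	6	Bra006452	TIR-NBS-LRR	A03	8631	9
AT5G41550.1	TIR-NBS-LRR	Chr5	3553	4	Bra028500	TIR-NBS-LRR	A07	4012	4
AT5G45230.1	TIR-NBS-LRR	Chr5	6156	6	Bra021956	TIR-NBS-LRR	A02	4277	5
AT5G45250.1	TIR-NBS-LRR	Chr5	4108	5	Bra027599	TIR-NBS-LRR	A09	3931	5
AT5G46450.1	TIR-NBS-LRR	Chr5	3928	5	Bra017542	TIR-NBS-LRR	A09	3362	5
AT5G46470.1	TIR-NBS-LRR	Chr5	7040	6	Bra017544	TIR-NBS-LRR	A09	5508	7
AT1G17600.1	TIR-NBS-LRR	Chr1	3322	4	Bra030998	TIR-NBS-LRR-NBS	A09	5997	8
AT4G36140.1	TIR-NBS-TIR-NBS-LRR	Chr4	5523	7	Bra011665	TIR-NBS-LRR-TIR	A01	4843	6
AT5G18370.1	TIR-NBS-LRR	Chr5	3890	4	Bra002153	TIR-NBS-NBS-LRR	A10	7583	7
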