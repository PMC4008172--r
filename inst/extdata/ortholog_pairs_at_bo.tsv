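ref_gene	ref_type	ref_location	ref_orf_length	ref_exons	counterpart	counterpart_type	counterpart_location	counterpart_orf_length	counterpart_exons
AT1G27170.1	TIR-NBS-LRR	Chr1	4858	5	Bol037684	TIR-NBS-LRR	NY	4783	5
AT1G50180.1	NBS	Chr1	2901	5	Bol011780	CC-NBS	C02	3507	3
AT1G63730.1	TIR-NBS-LRR	Chr1	3362	4	Bol022619	NBS-LRR	NY	4656	3
AT1G72870.1	TIR-NBS	Chr1	2161	2	Bol026308	TIR-NBS	C06	2317	2
AT1G72890.1	TIR-NBS	Chr1	1770	2	Bol026304	NBS	C06	830	2
AT1G72890.1	TIR-NBS	Chr1	1770	2	Bol040038	TIR-NBS	C06	1565	3
AT1G72950.1	TIR-NBS	Chr1	1395	2	Bol026303	TIR-NBS	C06	1232	2
AT1G72950.1	TIR-NBS	Chr1	1395	2	Bol040042	TIR-NBS	C06	2357	3
AT2G17060.1	TIR-NBS-LRR	Chr2	4466	6	Bol023868	CC-NBS-LRR	C06	2938	2
AT3G14460.1	NBS-LRR	Chr3	4274	1	Bol005097	NBS-LRR	C05	3623	1
AT3G14470.1	NBS-LRR	Chr3	3307	1	Bol005098	NBS	C05	9997	3
AT3G46730.1	NBS	Chr3	2543	1	Bol041411	NBS	C03	164	1
AT3G46730.1	NBS	Chr3	2543	1	Bol018762	NBS	C01	869	1
AT3G51560.1	TIR-NBS-LRR	Chr3	4105	5	Bol010610	TIR-NBS-LRR	NY	5368	4
AT3G51570.1	TIR-NBS-LRR	Chr3	4098	5	Bol010611	TIR-NBS	NY	4246	6
AT4G12010.1	TIR-NBS-LRR	Chr4	4182	5	Bol008302	TIR-NBS-LRR	NY	5143	5
AT4G12010.1	TIR-NBS-LRR	Chr4	4182	5	Bol030522	TIR-NBS-LRR	C03	3222	4
AT4G12020.2	NBS-LRR	Chr4	7992	16	Bol030521	NBS	C03	4504	6
AT4G19050.1	NBS-LRR	Chr4	3684	2	Bol009352	NBS-LRR	C01	3341	1
AT4G19500.1	TIR-NBS-TIR-NBS-LRR	Chr4	4736	5	Bol003710	NBS-LRR	NY	4676	3
AT4G19500.1	TIR-NBS-TIR-NBS-LRR	Chr4	4736	5	Bol024375	TIR-NBS-LRR	C07	4087	6
AT4G19500.1	TIR-NBS-TIR-NBS-LRR	Chr4	4736	5	Bol029862	TIR-NBS-LRR	C03	2445	4
AT4G19510.1	TIR-NBS-LRR	Chr4	5316	6	Bol003711	TIR-NBS	NY	3941	4
AT4G19510.1	TIR-NBS-LRR	Chr4	5316	6	Bol024376	NBS	C07	3424	4
AT4G19510.1	TIR-NBS-LRR	Chr4	5316	6	Bol029861	TIR-NBS	C03	3947	5
AT4G19520.1	TIR-NBS-LRR	Chr4	4421	4	Bol024371	TIR-NBS-LRR	C07	13901	6
AT4G19530.1	TIR-CC-NBS-LRR	Chr4	5538	5	Bol024372	TIR-NBS-LRR	C07	6114	4
AT4G26090.1	CC-NBS-LRR	Chr4	3534	1	Bol039594	CC-NBS-LRR	C01	2723	1
AT4G27190.1	CC-NBS-LRR	Chr4	2957	1	Bol042325	CC-NBS-LRR	C07	3053	1
AT4G33300.1	NBS-LRR	Chr4	5475	5	Bol013568	NBS	C01	2067	5
AT4G36140.1	TIR-NBS-TIR-NBS-LRR	Chr4	5523	7	Bol018676	NBS-LRR	C07	4440	7
AT5G04720.1	NBS	Chr5	3172	5	Bol002454	NBS-LRR	NY	3733	5
AT5G17880.1	TIR-NBS-LRR	Chr5	4225	6	Bol019768	TIR-NBS	C09	2856	5
AT5G17880.1	TIR-NBS-LRR	Chr5	4225	6	Bol034463	TIR-NBS-LRR	C03	2203	3
AT5G17970.1	TIR-NBS-LRR	Chr5	2620	4	Bol021382	NBS-NBS	C02	4845	2
AT5G45200.1	TIR-NBS-LRR	Chr5	6365	5	Bol032050	TIR-NBS-LRR	C09	9525	4
AT5G45210.1	TIR-NBS-LRR	Chr5	2913	4	Bol032051	TIR-NBS	C09	5857	4
AT5G45240.1	TIR-NBS-LRR	Chr5	5383	10	Bol005623	NBS	C07	2409	3
AT5G45250.1	TIR-NBS-LRR	Chr5	4108	5	Bol032054	TIR-NBS	C09	4575	6
AT5G45490.1	NBS	Chr5	1394	1	Bol022842	NBS	C02	728	1
AT5G46450.1	TIR-NBS-LRR	Chr5	3928	5	Bol032126	NBS-LRR	C09	2893	3
AT5G46470.1	TIR-NBS-LRR	Chr5	7040	6	Bol032125	NBS	C09	671	2
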