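global_environment	mag_id	lca_label	completeness	contamination	total_length	n_contigs	n50	n_proteins	pathway_completeness	steroid_degrader
Aerobic WWTP	WWT_1.17	f__Sphingomonadaceae	53.79	0	3,185,176	607	5,709	3,363	7	Yes
Aerobic WWTP	WWT_2.6	f__Oceanospirillaceae	68.49	2.94	2,676,165	573	4,917	3,072	8	Yes
Aerobic WWTP	WWT_4.10	f__Oceanospirillaceae	75.87	5.85	4,006,600	673	6,893	4,337	9	Yes
Aerobic WWTP	WWT_7.32	p__Actinobacteria	96.58	8.12	5,572,474	249	85,999	5,464	9	No
Aerobic WWTP	WWT_7.3	p__Actinobacteria	93.16	9.83	4,233,906	207	626,926	4,650	6	No
Aerobic WWTP	WWT_7.2	c__Betaproteobacteria	62.73	6.23	3,448,847	701	5,345	3,900	6	Yes
Aerobic WWTP	WWT_13.7	f__Rhodocyclaceae	51.23	9.13	3,553,647	538	7,567	3,957	6	Yes
Aerobic WWTP	WWT_19.1	g__Pseudomonas	53.45	0	4,731,881	602	9,957	4,775	8	No
Aerobic WWTP	WWT_18.119	g__Nocardioides	53.23	9.2	2,969,492	395	9,565	3,110	8	Yes
Peat soil	SOI_6.11	c__Actinobacteria	33.62	7.76	4,547,698	979	4,753	5,194	6	No
Peat soil	SOI_6.79	c__Alphaproteobacteria	47.3	5.17	2,223,633	349	7,406	2,383	6	Yes
Temperate forest soil	SOI_9.15	g__Mycobacterium	26.84	3.23	1,057,590	253	4,160	1,168	7	Yes
Antarctic Dry Valley soil	SOI_11.1	g__Rhodococcus	99.94	5.03	7,116,951	114	122,177	6,768	10	Yes
Antarctic Dry Valley soil	SOI_12.1	g__Rhodococcus	99.94	1.13	6,989,039	107	137,512	6,664	10	Yes
Deep ocean	DEO_2.4	g__Rhodococcus	85.92	2.79	5,065,927	753	8,048	5,413	10	Yes
Deep ocean	DEO_3.1	g__Rhodococcus	66.99	1.17	3,883,956	805	4,953	4,325	9	Yes
Deep ocean	DEO_4.4	g__Rhodococcus	91.76	2.71	4,585,835	544	10,691	4,668	10	Yes
Deep ocean	DEO_6.5	g__Rhodococcus	61.53	1.84	3,607,454	817	4,526	4,137	9	Yes
Deep ocean	DEO_7.4	g__Rhodococcus	82.37	1.89	3,841,856	289	20,213	3,817	10	Yes
Deep ocean	DEO_7.5	f__Nocardioidaceae	77.5	1.99	2,700,782	549	5,207	2,967	8	Yes
Deep ocean	DEO_8.1	g__Rhodococcus	98.98	2.71	5,531,222	381	21,692	5,499	10	Yes
Deep ocean	DEO_9.5	g__Rhodococcus	82.35	1.02	3,377,590	267	16,836	3,281	8	Yes
Marine oil seep	OPO_7.56	f__Rhodobacteraceae	41.06	5.73	2,641,776	244	32,960	2,696	7	Yes
Oxygen minimum zone	OMZ_4.28	p__Proteobacteria	81.01	9.87	3,893,890	574	8,445	4,045	9	Yes
Oxygen minimum zone	OMZ_5.19	p__Proteobacteria	39.71	1.41	1,628,638	363	4,714	1,815	6	Yes
Lentic	LEN_1.3	d__Bacteria	64.23	2.47	2,391,978	554	4,404	2,323	9	Yes
Thermal spring	THS_1.35	g__Mycobacterium	41.78	3.64	3,007,048	652	4,595	3,358	6	Yes
Thermal spring	THS_1.174	g__Mycobacterium	88.91	8.27	4,404,794	590	10,309	4,448	10	Yes
Deep subsurface	DES_1.10	f__Rhodobacteraceae	82.53	3.61	2,393,238	346	8,887	2,542	7	Yes
Sponge (Sarcotragus)	MSP_1.34	p__Actinobacteria	94.02	2.56	3,648,331	87	110,111	3,524	7	Yes
Sponge (Sarcotragus)	MSP_1.33	p__Proteobacteria	95.27	3.73	4,164,014	217	45,254	3,959	7	Yes
Sponge (Sarcotragus)	MSP_1.27	p__Proteobacteria	84.12	1.92	2,651,844	353	8,944	2,614	7	Yes
Sponge (Sarcotragus)	MSP_1.38	p__Proteobacteria	99.35	4.6	4,649,636	270	40,894	4,439	6	Yes
Sponge (Sarcotragus)	MSP_1.29	p__Proteobacteria	97.51	1.74	3,815,537	194	30,307	3,691	6	Yes
Sponge (Petrosia)	MSP_2.29	d__Bacteria	60.26	2.56	2,480,936	132	33,781	2,374	7	Yes
Sponge (Petrosia)	MSP_2.40	p__Proteobacteria	57.15	1.71	2,281,694	468	5,157	2,455	7	Yes
Sponge (Aplysina)	MSP_4.19	d__Bacteria	94.44	0.85	4,165,649	63	132,205	3,873	6	Yes
Sponge (Aplysina)	MSP_4.73	d__Bacteria	93.03	3.53	5,571,763	126	96,451	5,617	8	Yes
Sponge (Aplysina)	MSP_4.39	p__Actinobacteria	92.59	3.42	3,973,924	264	31,801	3,913	6	Yes
Sponge (Aplysina)	MSP_4.14	p__Proteobacteria	92.62	0.5	4,493,106	192	44,772	4,413	9	Yes
Sponge (Aplysina)	MSP_4.50	p__Proteobacteria	91.28	5.43	4,468,188	348	21,113	4,308	9	Yes
Rhizosphere	RHI_3.1	o__Sphingomonadales	31.3	5.17	3,865,039	737	5,362	4,414	8	Yes
Rhizosphere	RHI_3.9	f__Sphingomonadaceae	67.79	1.41	2,455,695	464	5,978	2,678	8	Yes
Rhizosphere	RHI_4.8	g__Mycobacterium	32.26	0.97	2,044,882	586	3,318	2,352	7	Yes
Rhizosphere	RHI_5.1	f__Sphingomonadaceae	83.88	7.59	3,936,626	718	6,077	4,370	8	Yes
Rhizosphere	RHI_6.17	o__Sphingomonadales	32.92	4.31	3,995,136	807	5,052	4,300	7	Yes
Rhizosphere	RHI_6.7	f__Sphingomonadaceae	81.88	2.18	3,031,208	564	5,796	3,353	7	Yes
Rhizosphere	RHI_7.12	o__Sphingomonadales	35.68	7.82	2,555,306	395	17,189	2,663	9	Yes
Termite gut	TER_1.13	c__Alphaproteobacteria	57.76	9.25	4,007,481	892	4,701	4,256	8	Yes
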