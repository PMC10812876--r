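event_id	lineage	gene_D	gene_S	gene_L	eD_1	eS_1	eL_1	eD_2	eS_2	eL_2	eD_3	eS_3	eL_3	eD_4	eS_4	eL_4	eD_5	eS_5	eL_5	eD_6	eS_6	eL_6
synthevent01	species1	geneD01	geneS01	geneL01	2.8532	2.9457	3.0003	3.8743	3.8204	3.839	2.7606	2.7245	2.6679	2.9316	3.0373	2.9378	3.1243	3.0869	2.9427	2.0151	1.9154	1.8938
synthevent02	species2	geneD02	geneS02	geneL02	1.9293	1.9597	2.9537	1.4947	1.7092	3.3418	3.5876	3.4173	3.7713	3.777	3.7141	1.6725	3.8127	3.7361	1.0548	3.657	3.631	2.3616
synthevent03	species1	geneD03	geneS03	geneL03	1.8108	1.7308	1.8813	3.7922	3.628	3.7763	1.1684	1.064	1.2329	3.1091	3.169	3.1088	1.0837	1.1873	1.1604	1.189	1.267	1.1622
synthevent04	species2	geneD04	geneS04	geneL04	3.0116	3.284	1.0597	1.9195	2.0359	1.8198	2.5324	2.5321	1.986	3.3149	3.3579	4.4181	2.0976	1.9211	2.6498	1.9022	1.814	2.8052
synthevent05	species1	geneD05	geneS05	geneL05	2.8729	2.7803	2.8676	2.9851	2.9692	2.9902	2.4992	2.665	2.6402	2.7477	2.7767	2.6975	3.9197	3.9675	3.8634	0.9592	1.1273	1.1556
synthevent06	species2	geneD06	geneS06	geneL06	3.0181	2.8814	3.7557	2.2131	2.1695	2.7121	3.2289	3.1012	2.8275	1.5242	1.5043	3.9308	1.4819	1.434	2.0932	1.4302	1.5249	3.8217
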