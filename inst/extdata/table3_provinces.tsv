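province	region	municipalities	population	density	n_tokens	tokens_per_capita	s_tokens	s_over_n	isonymy	entropy
Albacete	Castilla—La Mancha	87	397493	332.53	696059	1.75	2890	0.00415	0.016301	5.612761
Alicante/Alacant	Valencia	141	1891477	80.16	2753076	1.46	9151	0.00332	0.007232	6.578898
Almería	Andalucía	102	667635	104.92	1023128	1.53	4204	0.00411	0.013206	5.69845
Araba/Álava	Pais Vasco/Basques	51	309635	26.95	503959	1.63	5567	0.01105	0.00724	6.705729
Asturias	Asturias	78	1080138	102.00	1920957	1.78	6224	0.00324	0.025725	5.427719
Ávila	Castilla y León	248	171815	21.45	267840	1.56	1693	0.00632	0.026546	4.974525
Badajoz	Extremadura	164	685246	31.90	1203833	1.76	3949	0.00328	0.007839	6.184083
Barcelona	Cataluña	311	5416447	715.42	301742	0.06	4061	0.01346	0.006367	6.584385
Bizkaia	Pais Vasco/Basques	112	1146421	520.86	1810854	1.58	9452	0.00522	0.006089	6.905668
Burgos	Castilla y León	371	373672	26.26	590646	1.58	3858	0.00653	0.009664	6.082197
Cáceres	Extremadura	221	412498	20.91	696303	1.69	2814	0.00404	0.010414	5.905415
Cádiz	Andalucía	44	1220467	167.21	2218350	1.82	6089	0.00275	0.007967	6.232632
Cantabria	Cantabria	102	582138	114.60	945248	1.62	4671	0.00494	0.012546	5.929513
Castellón/Castelló	Valencia	135	594915	91.13	867299	1.46	5821	0.00671	0.004314	6.8022
Ciudad Real	Castilla—La Mancha	102	522343	26.96	886695	1.70	3312	0.00374	0.009924	5.968138
Córdoba	Andalucía	75	798822	58.51	1473060	1.84	4186	0.00284	0.007301	6.120176
Coruña (A)	Galicia	94	1139121	145.01	2029253	1.78	4994	0.00246	0.008848	6.165282
Cuenca	Castilla—La Mancha	238	215274	12.79	324160	1.51	2079	0.00641	0.012363	5.844352
Gipuzkoa	Pais Vasco/Basques	88	701056	356.37	1066577	1.52	7283	0.00683	0.003606	7.024319
Girona	Cataluña	221	731864	128.04	821377	1.12	6811	0.00829	0.004763	6.82443
Granada	Andalucía	168	901220	73.17	1531544	1.70	3918	0.00256	0.012391	5.726686
Guadalajara	Castilla—La Mancha	288	237787	21.01	310916	1.31	3010	0.00968	0.011244	5.974349
Huelva	Andalucía	79	507915	51.52	860123	1.69	3553	0.00413	0.011199	5.771795
Huesca	Aragón	202	225271	14.60	276891	1.23	3530	0.01275	0.003198	6.883493
Jaén	Andalucía	97	667438	49.69	1206451	1.81	3193	0.00265	0.009574	5.899168
Rioja (La)	Rioja	174	317501	64.02	478477	1.51	4135	0.00864	0.009702	6.20085
León	Castilla y León	211	500200	31.95	834196	1.67	3264	0.00391	0.022666	5.34661
Lleida	Cataluña	231	426872	36.53	496441	1.16	5871	0.01183	0.003101	7.149126
Lugo	Galicia	67	355549	35.66	619753	1.74	2357	0.00380	0.022581	5.34707
Madrid	Madrid	179	6271638	808.32	2575022	0.41	10114	0.00393	0.009428	6.388433
Málaga	Andalucía	101	1563261	222.33	2508900	1.60	7438	0.00297	0.008479	6.144749
Murcia	Murcia	45	1426109	129.94	2426454	1.70	6650	0.00274	0.014517	5.897324
Navarra	Navarra	272	620377	61.03	875044	1.41	6509	0.00744	0.004311	7.012149
Ourense	Galicia	92	336099	45.63	581330	1.73	2147	0.00369	0.024442	5.130659
Palencia	Castilla y León	191	173454	21.32	272273	1.57	2006	0.00737	0.011211	5.797694
Pontevedra	Galicia	62	953400	214.37	1710057	1.79	5019	0.00294	0.011019	6.014782
Salamanca	Castilla y León	362	353404	28.58	578092	1.64	2548	0.00441	0.027121	5.137096
Segovia	Castilla y León	209	163899	23.72	231590	1.41	1696	0.00732	0.014007	5.549435
Sevilla	Andalucía	105	1875462	137.43	3385166	1.80	8302	0.00245	0.008563	6.220057
Soria	Castilla y León	183	94646	9.23	137558	1.45	1393	0.01013	0.010763	5.653739
Tarragona	Cataluña	184	788895	128.75	1020551	1.29	7542	0.00739	0.004505	6.934706
Teruel	Aragón	236	146324	9.77	193834	1.32	2147	0.01108	0.005673	6.233202
Toledo	Castilla—La Mancha	204	670203	46.01	1009269	1.51	4194	0.00416	0.014376	5.759388
Valencia/València	Valencia	266	2543209	240.10	2134762	0.84	7114	0.00333	0.00615	6.626234
Valladolid	Castilla y León	225	529019	65.95	892428	1.69	4706	0.00527	0.010633	6.084073
Zamora	Castilla y León	248	197221	18.31	311923	1.58	1873	0.00601	0.012807	5.631792
Zaragoza	Aragón	293	955323	56.34	1560327	1.63	10372	0.00665	0.003952	7.198151
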