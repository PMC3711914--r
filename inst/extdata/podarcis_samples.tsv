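specimen_id	locality_code	locality_name	lat	lon	clade_id	cytb	nd4	mc1r	acm4	pdc
DB16840	1	Vieille-Roche (France)	47.5	-2.38	1	KF372191	KF372350	KF372113	KF372273	KF372036
DB16841	1	Vieille-Roche (France)	47.5	-2.38	1	KF372192	KF372351	KF372114	KF372274	KF372037
DB4296	2	Palacios de Compludo (Spain)	42.46	-6.47		KF372193	KF372352	KF372115	KF372275	KF372038
DB15980	3	Braña de Sosas (Spain)	43	-6.31	2	KF372194	KF372353	KF372116	KF372276	KF372039
DB15977	4	Señora de Carrasconte (Spain)	42.94	-6.23	2	KF372195	KF372354	KF372117	KF372277	KF372040
DB4281	5	La Omañuela (Spain)	42.78	-5.98	2	KF372196	KF372355	KF372118	-	-
DB4295	6	León (Spain)	42.59	-5.58	2	KF372197	KF372356	KF372119	KF372278	KF372041
DB15968	7	La Candamia (Spain)	42.6	-5.55	2	KF372198	KF372357	KF372120	KF372279	KF372042
DB15969	8	Valdehuesa (Spain)	42.94	-5.32	2	KF372199	KF372358	KF372121	KF372280	KF372043
DB15970	8	Valdehuesa (Spain)	42.94	-5.32	2	KF372200	KF372359	KF372122	KF372281	KF372044
DB8970	9	Tanes (Spain)	43.21	-5.4	2	KF372201	-	KF372123	KF372282	KF372045
DB8971	9	Tanes (Spain)	43.21	-5.4	2	KF372202	KF372360	KF372124	KF372283	KF372046
DB7092	10	Turieno (Spain)	43.16	-4.66		-	KF372361	KF372125	KF372284	KF372047
DB5880	11	Matienzo (Spain)	43.33	-3.59	2	KF372203	KF372362	KF372126	KF372285	KF372048
DB5882	11	Matienzo (Spain)	43.33	-3.59	2	KF372204	KF372363	KF372127	KF372286	KF372049
DB7065	12	Oriñon (Spain)	43.4	-3.33	2	KF372205	KF372364	KF372128	KF372287	KF372050
DB8957	13	Guadarrama (Spain)	40.71	-4.14	3	KF372206	KF372365	KF372129	KF372288	KF372051
DB8958	13	Guadarrama (Spain)	40.71	-4.14	3	KF372207	KF372366	KF372130	KF372289	KF372052
DB8959	13	Guadarrama (Spain)	40.71	-4.14	3	KF372208	KF372367	-	-	-
DB13472	14	Gúdar (Spain)	40.37	-0.67	3	-	-	KF372131	-	KF372053
DB13473	14	Gúdar (Spain)	40.37	-0.67	3	KF372209	KF372368	KF372132	KF372290	KF372054
DB13477	15	Penyagolosa (Spain)	40.23	-0.35	3	KF372210	KF372369	KF372133	KF372291	KF372055
DB13478	15	Penyagolosa (Spain)	40.23	-0.35	3	KF372211	KF372370	KF372134	KF372292	KF372056
DB14060	16	Montseny (Spain)	41.77	2.44	1	KF372212	KF372371	KF372135	KF372293	KF372057
DB14063	16	Montseny (Spain)	41.77	2.44	1	KF372213	KF372372	KF372136	KF372294	KF372058
DB14064	16	Montseny (Spain)	41.77	2.44	1	KF372214	KF372373	KF372137	KF372295	KF372059
DB1759	17	Les Salines (Spain)	42.42	2.75		KF372215	-	-	-	-
DB5030	18	Meranges (Spain)	42.43	1.78	1	KF372216	KF372374	KF372138	KF372296	KF372060
DB11195	18	Meranges (Spain)	42.43	1.78	1	KF372217	KF372375	KF372139	KF372297	-
DB13718	19	Luzenac (France)	42.75	1.75		KF372218	KF372376	-	-	-
DB13461	20	Massif des Maures (France)	43.24	6.38	6	KF372219	KF372377	KF372140	KF372298	KF372061
DB13460	21	Valle de Gilly (France)	43.28	6.46	6	KF372220	KF372378	KF372141	KF372299	KF372062
DB13430	22	Massif des Maures (France)	43.38	6.62	6	KF372221	KF372379	KF372142	KF372300	KF372063
DPM1	23	Viozene (Italy)	44.14	7.78	5	KF372222	-	KF372143	KF372301	KF372064
DPM3	23	Viozene (Italy)	44.14	7.78	5	KF372223	KF372380	KF372144	KF372302	KF372065
DB15936	24	Monte Verita (Switzerland)	46.16	8.72		KF372224	-	-	-	-
DB16837	25	Bianzano (Italy)	45.77	9.92	5	KF372225	KF372381	KF372145	KF372303	KF372066
DB16838	25	Bianzano (Italy)	45.77	9.92	5	KF372226	KF372382	KF372146	KF372304	-
DPM36	26	Peschiera del Garda (Italy)	45.44	10.67	5	KF372227	KF372383	KF372147	KF372305	KF372067
DPM37	26	Peschiera del Garda (Italy)	45.44	10.67	5	KF372228	KF372384	-	KF372306	KF372068
DPM38	26	Peschiera del Garda (Italy)	45.44	10.67	5	KF372229	KF372385	KF372148	KF372307	KF372069
DB1399	27	Ostia Antica (Italy)	41.75	12.31	9	KF372230	KF372386	KF372149	KF372308	KF372070
DB5938	28	Paganico (Italy)	42.19	13	9	KF372231	KF372387	KF372150	KF372309	KF372071
DPM39	29	Majelletta (Italy)	42.16	14.13	10	KF372232	KF372388	KF372151	KF372310	KF372072
DPM40	29	Majelletta (Italy)	42.16	14.13	10	KF372233	KF372389	KF372152	KF372311	KF372073
DPM41	29	Majelletta (Italy)	42.16	14.13	10	KF372234	-	-	-	KF372074
DPM15	30	Bassiano (Italy)	41.55	13.05	9	KF372235	KF372390	KF372153	KF372312	KF372075
DPM16	30	Bassiano (Italy)	41.55	13.05	9	KF372236	KF372391	KF372154	KF372313	KF372076
DPM18	31	Fondi (Italy)	41.37	13.33	9	KF372237	KF372392	KF372155	KF372314	KF372077
DPM19	31	Fondi (Italy)	41.37	13.33	9	KF372238	KF372393	KF372156	KF372315	KF372078
DPM25	32	Pollino National Park (Italy)	39.93	16.17	7	KF372239	KF372394	KF372157	KF372316	KF372079
DB5937	33	Pollino National Park (Italy)	39.9	16.19	7	KF372240	KF372395	KF372158	KF372317	KF372080
DPM21	33	Pollino National Park (Italy)	39.9	16.19	7	KF372241	KF372396	KF372159	KF372318	KF372081
DPM7	34	Fago del Soldato (Italy)	39.35	16.55	8	KF372242	KF372397	KF372160	KF372319	KF372082
DPM8	34	Fago del Soldato (Italy)	39.35	16.55	8	KF372243	KF372398	KF372161	KF372320	KF372083
DPM6	34	Fago del Soldato (Italy)	39.35	16.55	8	KF372244	KF372399	KF372162	KF372321	KF372084
DB13929	35	Ribnica (Slovenia)	45.75	14.77	11	KF372245	KF372400	KF372163	KF372322	KF372085
DB13930	35	Ribnica (Slovenia)	45.75	14.77	11	KF372246	KF372401	KF372164	KF372323	KF372086
DB13943	36	Donja Lamana Draga (Slovenia)	45.51	14.96	11	KF372247	KF372402	KF372165	KF372324	KF372087
DB13945	36	Donja Lamana Draga (Slovenia)	45.51	14.96	11	KF372248	KF372403	KF372166	KF372325	KF372088
DB15991	37	Zuce (Serbia)	44.68	20.55	4	KF372249	KF372404	KF372167	KF372326	KF372089
DB15992	37	Zuce (Serbia)	44.68	20.55	4	KF372250	KF372405	KF372168	KF372327	KF372090
DB15993	37	Zuce (Serbia)	44.68	20.55	4	KF372251	KF372406	KF372169	KF372328	KF372091
DB13309	38	Cиheвo (Serbia)	43.34	22.08	4	KF372252	KF372407	KF372170	KF372329	KF372092
DB16121	39	Road to Crnovska River (Serbia)	42.38	22.05	4	KF372253	KF372408	KF372171	KF372330	KF372093
DB16122	39	Road to Crnovska River (Serbia)	42.38	22.05	4	KF372254	KF372409	KF372172	KF372331	KF372094
DB16123	39	Road to Crnovska River (Serbia)	42.38	22.05	4	KF372255	KF372410	KF372173	KF372332	KF372095
DPM31	40	Metsovo (Greeece)	39.71	21.19	13	KF372256	KF372411	KF372174	KF372333	KF372096
DPM32	41	Metsovo (Greeece)	39.71	21.21	13	KF372257	KF372412	KF372175	KF372334	KF372097
DB16934	42	Velouxi (Greece)	38.85	21.38	14	KF372258	KF372413	-	KF372335	KF372098
DPM34	43	Platanitsa, Achaia (Greece)	37.97	21.88	14	KF372259	KF372414	KF372176	KF372336	KF372099
DPM35	44	Platanitsa, Achaia (Greece)	37.96	21.91	14	KF372260	-	KF372177	KF372337	KF372100
DB16936	45	Mainalo, Pelloponnisos (Greece)	37.39	22.46	14	KF372261	KF372415	-	-	-
DB16933	46	Kisavos mt (Greece)	39.63	22.64	12	KF372262	KF372416	-	-	-
DB16938	47	Samothraki isl. (Greece)	40.45	25.59	16	KF372263	KF372417	KF372178	KF372338	-
DB16310	48	Kapakli (Turkey)	41.89	27.35	15	KF372264	KF372418	KF372179	KF372339	KF372101
DB16307	49	Kapakli (Turkey)	41.91	27.36	15	KF372265	KF372419	KF372180	KF372340	KF372102
DB16311	50	Dereköy (Turkey)	41.96	27.39	15	KF372266	KF372420	KF372181	KF372341	KF372103
DB16317	50	Dereköy (Turkey)	41.96	27.39	15	KF372267	KF372421	KF372182	KF372342	KF372104
DB16482	50	Dereköy (Turkey)	41.96	27.39	15	-	KF372422	KF372183	KF372343	KF372105
DB16322	51	Dereköy (Turkey)	41.97	27.42	15	KF372268	KF372423	KF372184	KF372344	KF372106
DB16332	51	Dereköy (Turkey)	41.97	27.42	15	KF372269	KF372424	KF372185	KF372345	KF372107
DB16485	51	Dereköy (Turkey)	41.97	27.42	15	KF372270	KF372425	KF372186	KF372346	KF372108
DB16318	52	Dereköy (Turkey)	41.96	27.45	15	-	KF372426	KF372187	KF372347	KF372109
DB16341	53	Pınarözü (Turkey)	41.77	34.04	17	KF372271	KF372427	KF372188	KF372348	KF372110
DB16340	53	Pınarözü (Turkey)	41.77	34.04	17	-	KF372428	KF372189	KF372349	KF372111
DB16451	53	Pınarözü (Turkey)	41.77	34.04	17	KF372272	KF372429	KF372190	-	KF372112
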