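human_symbol	mouse_symbol
IL10	
IL10RA	
IL10RB	
CD40	
CD40LG	Cd40lg
ICOS	
ICOSLG	
CD8A	
LCK	
MALT1	
CARD11	
BCL10	
IL21	
IL21R	
NLRP12	
CXCR2	
CR2	
BTK	
WAS	
WIPF1	
ADA	
RAG1	
RAG2	
IL2RG	
IL7R	
JAK3	
PTPRC	
CD3D	
CD3E	
CD3G	
ZAP70	
LIG4	
NHEJ1	
DCLRE1C	
AK2	
FOXN1	
CORO1A	
CIITA	
RFXANK	
RFX5	
RFXAP	
TAP1	
TAP2	
TAPBP	
B2M	
DOCK8	
STAT1	
STAT3	
STAT5B	
IL12B	
IL12RB1	
IFNGR1	
IFNGR2	
IRF8	
GATA2	
ELANE	
HAX1	
G6PC3	
SBDS	
VPS45	
JAGN1	
CSF3R	
CYBB	
CYBA	
NCF1	
NCF2	
NCF4	
RAC2	
ITGB2	
MPO	
TLR3	
UNC93B1	
TBK1	
IRF3	
IRF7	
STAT2	
IFIH1	
CARD9	
IL17F	
IL17RA	
STK4	
RORC	
AIRE	
FOXP3	
CTLA4	
LRBA	
IL2RA	
PIK3CD	
PIK3R1	
PTEN	
CD19	
CD81	
MS4A1	
TNFRSF13B	
TNFRSF13C	
NFKB1	
NFKB2	
IKBKB	
IKBKG	Ikbkg
NFKBIA	
MYD88	
IRAK4	
C1QA	
C1QB	
C1QC	
C2	
C3	
C5	
C6	
C7	
C8A	C8a
C8B	C8b
C9	
CFB	
CFD	
CFH	
CFI	
CFP	
MASP2	
SERPING1	
CD46	
CD55	
CD59	
NLRP3	
MEFV	
MVK	
NOD2	
PSTPIP1	
IL1RN	
NLRC4	
PLCG2	
ADAR	
TREX1	
SAMHD1	
USP18	
ISG15	
PSMB8	
SEMA3E	
PRF1	
UNC13D	
STX11	
STXBP2	
LYST	
RAB27A	
AP3B1	
SH2D1A	
XIAP	
ITK	
MAGT1	
CD27	
CD70	
CTPS1	
RASGRP1	
CXCL8	
SYNIEI001	Altname1
SYNIEI002	Altname2
SYNIEI003	
SYNIEI004	
SYNIEI005	
SYNIEI006	
SYNIEI007	
SYNIEI008	
SYNIEI009	
SYNIEI010	
SYNIEI011	
SYNIEI012	
SYNIEI013	
SYNIEI014	
SYNIEI015	
SYNIEI016	
SYNIEI017	
SYNIEI018	
SYNIEI019	
SYNIEI020	
SYNIEI021	
SYNIEI022	
SYNIEI023	
SYNIEI024	
SYNIEI025	
SYNIEI026	
SYNIEI027	
SYNIEI028	
SYNIEI029	
SYNIEI030	
SYNIEI031	
SYNIEI032	
SYNIEI033	
SYNIEI034	
SYNIEI035	
SYNIEI036	
SYNIEI037	
SYNIEI038	
SYNIEI039	
SYNIEI040	
SYNIEI041	
SYNIEI042	
SYNIEI043	
SYNIEI044	
SYNIEI045	
SYNIEI046	
SYNIEI047	
SYNIEI048	
SYNIEI049	
SYNIEI050	
SYNIEI051	
SYNIEI052	
SYNIEI053	
SYNIEI054	
SYNIEI055	
SYNIEI056	
SYNIEI057	
SYNIEI058	
SYNIEI059	
SYNIEI060	
SYNIEI061	
SYNIEI062	
SYNIEI063	
SYNIEI064	
SYNIEI065	
SYNIEI066	
SYNIEI067	
SYNIEI068	
SYNIEI069	
SYNIEI070	
SYNIEI071	
SYNIEI072	
SYNIEI073	
SYNIEI074	
SYNIEI075	
SYNIEI076	
SYNIEI077	
SYNIEI078	
SYNIEI079	
SYNIEI080	
SYNIEI081	
SYNIEI082	
SYNIEI083	
SYNIEI084	
SYNIEI085	
SYNIEI086	
SYNIEI087	
SYNIEI088	
SYNIEI089	
SYNIEI090	
SYNIEI091	
SYNIEI092	
SYNIEI093	
SYNIEI094	
SYNIEI095	
SYNIEI096	
SYNIEI097	
SYNIEI098	
SYNIEI099	
SYNIEI100	
SYNIEI101	
SYNIEI102	
SYNIEI103	
SYNIEI104	
SYNIEI105	
SYNIEI106	
SYNIEI107	
SYNIEI108	
SYNIEI109	
SYNIEI110	
SYNIEI111	
SYNIEI112	
SYNIEI113	
SYNIEI114	
SYNIEI115	
SYNIEI116	
SYNIEI117	
SYNIEI118	
SYNIEI119	
SYNIEI120	
SYNIEI121	
SYNIEI122	
SYNIEI123	
SYNIEI124	
SYNIEI125	
SYNIEI126	
SYNIEI127	
SYNIEI128	
SYNIEI129	
SYNIEI130	
SYNIEI131	
SYNIEI132	
SYNIEI133	
SYNIEI134	
SYNIEI135	
SYNIEI136	
SYNIEI137	
SYNIEI138	
SYNIEI139	
SYNIEI140	
SYNIEI141	
SYNIEI142	
SYNIEI143	
SYNIEI144	
SYNIEI145	
SYNIEI146	
SYNIEI147	
SYNIEI148	
SYNIEI149	
SYNIEI150	
SYNIEI151	
SYNIEI152	
SYNIEI153	
SYNIEI154	
SYNIEI155	
SYNIEI156	
SYNIEI157	
SYNIEI158	
SYNIEI159	
SYNIEI160	
SYNIEI161	
SYNIEI162	
SYNIEI163	
SYNIEI164	
SYNIEI165	
SYNIEI166	
SYNIEI167	
SYNIEI168	
SYNIEI169	
SYNIEI170	
SYNIEI171	
SYNIEI172	
SYNIEI173	
SYNIEI174	
SYNIEI175	
SYNIEI176	
SYNIEI177	
SYNIEI178	
SYNIEI179	
SYNIEI180	
SYNIEI181	
SYNIEI182	
SYNIEI183	
SYNIEI184	
SYNIEI185	
SYNIEI186	
SYNIEI187	
SYNIEI188	
SYNIEI189	
SYNIEI190	
SYNIEI191	
SYNIEI192	
SYNIEI193	
SYNIEI194	
SYNIEI195	
SYNIEI196	
SYNIEI197	
SYNIEI198	
SYNIEI199	
SYNIEI200	
SYNIEI201	
SYNIEI202	
SYNIEI203	
SYNIEI204	
SYNIEI205	
SYNIEI206	
SYNIEI207	
SYNIEI208	
SYNIEI209	
SYNIEI210	
SYNIEI211	
SYNIEI212	
SYNIEI213	
SYNIEI214	
SYNIEI215	
SYNIEI216	
SYNIEI217	
SYNIEI218	
SYNIEI219	
SYNIEI220	
SYNIEI221	
SYNIEI222	
SYNIEI223	
SYNIEI224	
SYNIEI225	
SYNIEI226	
SYNIEI227	
SYNIEI228	
SYNIEI229	
SYNIEI230	
SYNIEI231	
SYNIEI232	
SYNIEI233	
SYNIEI234	
SYNIEI235	
SYNIEI236	
SYNIEI237	
SYNIEI238	
SYNIEI239	
SYNIEI240	
SYNIEI241	
SYNIEI242	
SYNIEI243	
SYNIEI244	
SYNIEI245	
SYNIEI246	
SYNIEI247	
SYNIEI248	
SYNIEI249	
SYNIEI250	
SYNIEI251	
SYNIEI252	
SYNIEI253	
SYNIEI254	
SYNIEI255	
SYNIEI256	
SYNIEI257	
SYNIEI258	
SYNIEI259	
SYNIEI260	
SYNIEI261	
SYNIEI262	
SYNIEI263	
SYNIEI264	
SYNIEI265	
SYNIEI266	
SYNIEI267	
SYNIEI268	
SYNIEI269	
SYNIEI270	
SYNIEI271	
SYNIEI272	
SYNIEI273	
SYNIEI274	
SYNIEI275	
SYNIEI276	
SYNIEI277	
SYNIEI278	
SYNIEI279	
SYNIEI280	
SYNIEI281	
SYNIEI282	
SYNIEI283	
SYNIEI284	
SYNIEI285	
SYNIEI286	
SYNIEI287	
SYNIEI288	
SYNIEI289	
SYNIEI290	
SYNIEI291	
SYNIEI292	
SYNIEI293	
SYNIEI294	
SYNIEI295	
SYNIEI296	
SYNIEI297	
SYNIEI298	
SYNIEI299	
SYNIEI300	
SYNIEI301	
SYNIEI302	
SYNIEI303	
SYNIEI304	
SYNIEI305	
SYNIEI306	
SYNIEI307	
SYNIEI308	
SYNIEI309	
SYNIEI310	
SYNIEI311	
SYNIEI312	
SYNIEI313	
SYNIEI314	
SYNIEI315	
SYNIEI316	
SYNIEI317	
SYNIEI318	
SYNIEI319	
SYNIEI320	
SYNIEI321	
SYNIEI322	
SYNIEI323	
SYNIEI324	
SYNIEI325	
SYNIEI326	
SYNIEI327	
SYNIEI328	
SYNIEI329	
SYNIEI330	
SYNIEI331	
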