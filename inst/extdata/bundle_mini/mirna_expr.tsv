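feature_id	case_01	case_02	case_03	case_04	case_05	case_06	case_07	case_08	ctrlA_01	ctrlA_02	ctrlA_03	ctrlA_04	ctrlA_05	ctrlA_06	ctrlA_07	ctrlA_08	ctrlB_01	ctrlB_02	ctrlB_03	ctrlB_04	ctrlB_05	ctrlB_06	ctrlB_07	ctrlB_08
mir001	10.944775683846411	11.801627985063325	10.219515845783125	10.426561983868401	11.057021297394432	9.1853463910625273	13.010230709247294	11.483827911634332	12.551221315477104	10.342799101638745	10.444326833471106	10.969096715783094	10.465695401169784	10.032283393912941	11.172052290635873	9.6440770266150739	12.210404824659976	9.4134763664507091	10.967734264162008	11.123996901087136	11.908071591388147	10.469779225863794	13.3149629895799	10.537014089048302
mir002	7.3354783395415133	10.321710578512821	7.2511906410404308	6.9402025427963689	9.3308930877533065	7.0848094784688644	7.1177534463146754	8.2094394236731958	7.4268145702375898	8.639484976735492	7.6340583034313836	7.698591157314473	7.0082172492532244	8.4150972026499318	9.54372486082889	8.849664322471229	9.2438201799895729	8.8720135468551149	8.3900805027594796	7.2353749838672519	8.5989507764067987	7.601074157022941	7.4312474176566967	9.1216095736914085
mir003	11.132936593189495	10.566576581733823	10.821102159272	10.218168369122267	10.992425729383539	11.604107769048948	11.132800399177096	10.768053989567168	12.377189379047685	12.206890759689074	12.084053901724811	11.742230940929545	13.190468412529116	9.9975376434287995	12.107943226015724	10.583798470415655	11.059796443677008	11.8119966663231	10.999856032939345	11.065130225285824	11.714601224891254	9.1959937554691429	12.531015409723416	10.25807659075879
mir004	8.6048742918919174	8.694093901002514	9.7260768678779783	8.76375430547467	8.4555771904029058	10.464326386925395	9.5745736781129995	9.1486360406906559	11.833703856637451	11.995316563161873	10.409857018985024	9.6090429382313118	8.8406831285879139	9.5435644419103731	8.511697440181349	12.094739035550553	11.867821771916409	7.9755387482000053	10.681000940209403	9.7477066842935152	7.9188658368666927	8.2468162308502642	9.1378935500325298	9.7495129973650325
mir005	8.8518901268626689	9.9429413508489866	9.2878840505953519	9.3099625856188997	9.4348403069482973	8.7115597981154984	7.9282402627302542	8.4608269374763836	7.8309652907280878	9.2811753015189833	9.4620994292899425	9.2684656967775059	8.9950745741222864	6.4384720487805325	7.2870006415486701	7.3886786124337007	8.3695665284558398	9.2099198775940465	8.3429796726512482	9.3073223848009938	8.7719968263755401	9.7002651846106609	10.037859181680027	7.5740676003230085
mir006	13.128377811571696	12.025008396251621	11.823193585334554	12.361558610953461	11.475775161097003	11.355055032577347	11.949231625778102	11.793900311465718	13.938488356503742	12.025345642117379	11.972433721178527	12.536767537592365	13.473250730077067	11.903860755510392	11.39170679029016	11.744201131104662	13.360588142458345	10.468743724023387	12.619769785603848	12.814239356604077	12.043352829982821	12.641282132300736	11.733612603964493	10.335244654168571
mir007	11.291145352357674	11.262861403444495	11.925718890938763	10.484163494169094	11.790293643926221	10.544770392379998	9.8414006385546315	9.6095694453575664	10.859954858649402	10.563151014102935	8.6636493452379391	11.455560741632588	10.608398252820399	11.040601901664704	9.3097527210999598	9.9688676408665611	9.5537554483060241	10.49671112667491	11.624965440679501	11.213162756254077	10.944108814712829	10.639833247913648	10.199443647767787	10.451022579798845
mir008	11.058101084350517	11.074364967261191	11.929006602645924	10.976409013575129	11.363005154966684	12.400916362001238	9.9155510638490245	11.218466072588429	9.5586083475361043	12.61139602136083	12.685852124967612	10.603820453417677	11.027837509698866	11.916430854472644	10.420969134135404	10.459863530688903	12.238950814360756	11.051977325049466	11.856547646511654	10.53868368400639	12.73415783757722	13.641179590260343	11.4798630634511	12.550063859617058
mir009	6.8313370404264493	5.7695482421238671	5.8448702633110701	5.4960618843994578	6.9421837865329401	4.0754289037443963	7.5907026454466253	5.6937900501291576	4.572055588559472	7.1620534524289186	6.7362780813805871	5.1948661532408336	6.6605533953241061	4.5550745149741001	4.695770328082169	6.902811074755177	4.5412963014501253	6.2589779987393594	7.6552374068404774	5.9862760622529727	5.7580704902074125	5.237364941760716	6.296639331393485	5.0378549707209483
mir010	8.4310506471397026	7.5408111826977127	7.6641421565137433	5.7810054175767656	6.4908385899263292	7.3957051665688347	7.5973996678161875	8.1089648794543194	7.4229264534960659	7.3599276520008132	6.0568343967882603	9.2114932167185284	6.2848218078339171	7.4419808449845286	6.8312789762599202	7.2858715103830196	7.1184251481718093	8.2043579203068706	7.8139968694522342	8.5503175472188477	7.1306383570769407	6.9789741913849008	8.9334585139276488	7.4377173073104927
mir011	4.2140642415342571	6.899091279148756	5.836706584285472	4.166941439333014	4.8168592571771649	6.3608993160137715	4.6213904931118392	4.8440690120183323	5.9557546666812824	4.3536716014849866	6.7686348184231635	4.9473349716884449	5.8779365891781028	7.0760933558454182	4.5992854871709445	5.248579053501679	5.5775908766361519	4.743185639309111	5.3159217485575132	5.4003459716536097	4.6709977660854776	4.5285472997391452	7.3523888309473922	4.9261691096845119
mir012	6.3250145612563058	7.0176457041279789	8.7995655131139312	5.6483518793545535	6.6293182193932125	6.8137600098496014	6.5654920194646182	4.3047782314283101	6.960965573974331	6.8505045730637883	6.5615856492175162	6.8735259802695987	8.4046325564762654	6.0061922561758632	6.7819202618761381	6.9536742253705244	6.0644143398962926	7.032719581890774	5.6781051208709563	8.5018362776939167	7.0888027647659264	7.9818084296592753	7.4969623857563468	5.6583793869715135
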