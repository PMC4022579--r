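feature_id	GC01_r1	GC01_r2	GC01_r3	GC02_r1	GC02_r2	GC02_r3	NGC01_r1	NGC01_r2	NGC01_r3	NGC02_r1	NGC02_r2	NGC02_r3	NC01_r1	NC01_r2	NC01_r3	NC02_r1	NC02_r2	NC02_r3
m0001	2.56296135029	2.04631600627	2.04733945878	1.19380161868	2.72692740986	1.51527165586	-0.036980870818	-0.230682047916	0.72943281436	0.503489239084	0.192562943925	0.203919682715	-0.75144337706	0.254637445056	0.604143692999	-0.842228468705	-0.440735301275	-0.448463269571
m0002	-2.00818768121	-2.11974552044	-1.98528143557	-1.14801414248	-1.55396924972	-1.97362668598	0.0449212274649	-0.611300588414	0.368901230505	-0.205225719351	0.900894794006	0.0884747994369	-1.06666689129	0.461045264547	0.432901328595	0.785363052007	0.682506335935	0.929367717371
m0003	0.33249258263	0.42091888631	 1.2039083446	0.332097507853	-0.23442809585	-0.614520400251	2.55704029375	2.26777784015	2.25113190696	1.71570081146	0.985513475065	1.80681213146	-0.141671689886	-0.146786223666	-0.214739335336	0.363404178109	-0.633407214854	-1.55082430314
m0004	-0.313396144288	0.530833230666	-0.507490796448	-0.600391981227	0.104926632169	-0.435468406511	-2.59893807961	-2.83807398869	-2.51490957898	-1.45995291519	-2.45426313324	-2.25233355229	0.800976231976	0.722119980789	0.0755717826691	-0.138912771345	0.344712043217	1.14603035788
m0005	-0.546172820703	0.576545951751	-0.251707801723	-0.434576500605	-1.09526312636	0.584707765781	-0.0341662439823	1.14578685671	1.06748675186	0.0278692049109	0.272394817393	0.799376320789	2.31756790668	1.65204229551	1.85927399744	1.43560845301	1.08351448699	  1.434251722
m0006	1.03000772895	-0.259054738907	-1.03809478786	0.936809382057	0.285192197621	0.0715005115049	0.277656318554	0.248351145799	0.175138092018	-0.916403167092	-0.901105975058	0.00948655857799	-2.96603059822	-1.37866083717	-2.99955568847	-2.81131769825	-2.15920944172	-2.13537109264
m0007	-0.0205310778526	-0.00726447589088	0.824030001621	0.0957436437077	-0.140360190804	0.053536816071	-0.177259037409	0.906844142449	 1.1815125239	0.523022293292	-0.20860371766	0.907851898116	0.495938174567	-0.731070174417	-0.179525486429	-0.126753619169	-1.00293183028	-0.216331020567
m0008	-0.400559175189	0.699290863659	-0.519460633058	-0.105086953253	-0.876497360739	-0.972950914302	-0.164125688685	-0.401623195014	0.38056820106	0.336887145354	0.146901249392	1.09986523893	0.823754634022	0.140047663718	0.271895052231	0.199885705811	1.11901348331	-0.628421377987
m0009	-0.0559585885555	-0.462664919015	 1.0341260113	-0.364931603147	-0.706189700232	-0.0502004977106	-0.956106384787	-0.351047681748	-0.495849472896	-0.707920172278	-0.510235198345	-1.22991381746	-0.712124890345	0.348063461203	-1.0465408177	0.616223676064	-0.678391716938	-0.129308674815
m0010	-0.512547179981	0.934290370413	-0.278838376112	0.266678117704	-0.287288030284	0.042813348623	-0.0843686039896	0.207180356208	0.0962799916728	-0.580314438626	0.335539980725	 1.1620815644	-0.574548916669	0.140575119991	-0.955935760224	1.50539966437	-0.0595135717225	-0.854577084351
m0011	-0.705400707043	-1.23026714944	-0.248623294609	0.199882224281	0.408243678834	0.528165220753	0.52750350647	0.305292480157	1.03109859655	0.211793648036	-0.716297355729	-0.189231186734	-0.713456206276	-0.57422133431	-0.524481130179	1.08800522442	-0.482274933435	-0.203478442226
m0012	0.377949040688	0.404529000357	0.883367807964	0.484477338649	1.17399533347	0.252200985034	0.204923681438	0.739526603467	0.502445457074	-0.319149747874	-0.711780963566	-0.123679439404	0.204431126966	0.0227767596866	0.00671703377104	-0.799296193883	-1.04667250155	0.525616703283
m0013	0.508723390071	-0.572407058862	-0.603665744501	 0.2599077336	-0.282871390541	0.838147487677	0.707570979114	0.309520048903	-0.368707645773	-0.466796080598	-0.107442949079	0.0503469871278	-0.504993520782	-0.352735228842	-0.634097552414	-0.193568975956	0.758074539346	0.0142578122199
m0014	-0.159497090707	0.565564118599	0.165948973103	0.000485765232561	-0.499976398886	-0.960286678506	0.204886438659	1.39990199752	1.64216638161	-0.529330006316	-0.350046904514	-0.52939765396	0.0626857254467	0.452692588232	-0.00828239916627	-0.447278099973	0.0976728503196	-1.01903156997
m0015	0.13858757741	0.431368873883	0.458171768131	0.38417379131	0.640817855279	-1.05754375339	0.268953461059	-0.349356277649	-0.226119586205	0.0499404597159	-0.97867255755	0.0392032298083	-0.666029472618	-0.489253888783	-0.055463970974	0.534564201305	0.272821697192	0.148891070437
m0016	0.0845235765626	0.422471099959	0.448338229167	0.475800060862	-0.18703988844	-0.0412486778284	0.150296957697	-0.191076023911	0.653438925331	-0.244756458242	0.533395586026	-0.932652635999	-0.139191974431	0.0352499915985	0.974392206873	0.284588111778	0.38447781832	0.0549037885646
m0017	0.798823557783	-0.0234344809393	-0.0729133968537	0.419051294415	-0.403920256789	0.39768592088	0.33780207911	-0.0277118213729	 0.5434825583	0.837613184098	0.659775057987	0.50327421453	0.614637229411	0.879718399364	-0.0868477571569	-0.513314582719	-0.864742573658	-0.0580731776565
m0018	0.147581968769	0.338886377669	0.232107318636	-0.166229848776	0.723784047716	-0.857741474137	0.152786568885	0.189594068721	0.376134155033	0.29735652002	0.257437338396	0.124506730407	-0.477986576593	0.49091042371	-1.34632367799	0.260913724789	0.837180619801	0.244364108784
m0019	1.06107519124	-0.509886567332	-0.218943526011	0.0209785549111	-0.897544254925	0.808563898375	-0.873550096442	0.421712663011	-0.315868586781	-0.526673508075	-0.588445801002	-1.43740618633	-0.458951059145	-0.0854881139597	-0.501721450419	0.214660576875	-0.471992103534	0.212509606125
m0020	-0.0952732574616	-1.14149439718	0.337826246718	-0.158896942306	-0.447187369422	-0.777292108331	0.361210704395	-0.256114896952	-0.649858188369	0.542596175071	0.164610822676	0.430244650855	0.899482541516	0.199731705191	0.179396520606	-0.626677629923	-0.174810090695	-0.0531102576467
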