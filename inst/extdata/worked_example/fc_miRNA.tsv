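feature_id	GC01_r1	GC01_r2	GC01_r3	GC02_r1	GC02_r2	GC02_r3	NGC01_r1	NGC01_r2	NGC01_r3	NGC02_r1	NGC02_r2	NGC02_r3	NC01_r1	NC01_r2	NC01_r3	NC02_r1	NC02_r2	NC02_r3
mir001	-2.06475485395	-2.30550425289	-1.56239604928	-1.87950873459	-1.56938912493	-1.55460494726	0.579282777756	0.443884845845	0.0366256834225	-0.0403380043716	-0.000670113476089	-0.149742998666	0.200296289704	-0.906521506714	0.32631722333	-0.318670361015	0.646592330034	0.710442248087
mir002	-0.100568323802	0.534448790465	-0.333906837912	1.00196867783	-0.428587528756	0.030295810367	-2.60934991256	-2.15365971333	-2.33120070686	-2.09479913695	-1.56185326077	-1.99430169192	0.270467339058	0.953238784778	0.647260398369	0.0980551972852	0.500610764737	0.755907895408
mir003	0.0904851814439	-0.335001134581	-0.0713889011559	-0.184607978475	-0.990127984724	0.0745788501493	-0.34444518048	-1.24103764787	0.797683124756	-0.571065471225	-0.607147053217	0.540548480239	-2.25299033449	-3.07883489637	-1.75326271966	-1.82039651067	-1.62435846585	-1.7767726985
mir004	-0.116019953651	-0.0474917688503	0.581054056962	-0.0950783667334	0.307654612982	0.147590427844	-0.187475957258	0.411126640522	-1.11259382092	-0.702246723228	-0.353718324606	-0.0202213915448	0.183821237459	0.802705174957	-0.377443457488	-0.00742991577809	-1.10874681583	-0.536409921149
mir005	0.525332445787	-0.104276722772	-0.0495441093861	-0.127820691051	0.157921844971	0.0247419116291	-0.00924842143568	-0.0998337615437	0.282075906512	0.0216985691368	-0.308218203832	-0.760576134589	0.805701419488	-0.428440667404	0.0870873281144	-0.327262824605	0.177508680048	-0.202664765706
mir006	-0.5116208197	-0.0607597589265	-0.138034124848	0.0686060797523	-0.706763673009	-0.568913588813	-1.23259103067	-0.28173896753	-0.608014542524	0.0511495512764	-0.746120526949	0.110483472366	0.260926768663	-0.448195090251	-0.366701662386	-0.472350970137	0.276077504671	-1.1457428087
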