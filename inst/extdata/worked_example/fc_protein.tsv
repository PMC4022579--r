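feature_id	GC01_r1	GC01_r2	GC01_r3	GC02_r1	GC02_r2	GC02_r3	NGC01_r1	NGC01_r2	NGC01_r3	NGC02_r1	NGC02_r2	NGC02_r3	NC01_r1	NC01_r2	NC01_r3	NC02_r1	NC02_r2	NC02_r3
p001	1.74447417499	1.15141202914	2.10552693694	2.14753235452	2.90486083792	2.24102905254	-0.0293299629516	0.52274735789	0.381613685173	-0.116522841844	-0.740539396783	-1.19801836532	-0.258401166979	-1.06179236271	-0.667563671891	-0.337168973871	-0.316337907035	0.447208109121
p002	-0.529166039391	-0.651725215514	-0.807708461229	-0.484964413166	0.366223994246	1.44626721127	3.43100483837	1.07302518484	 1.6168420309	2.01186909842	2.15489390424	2.04067888777	-0.246060341226	-0.941008142574	0.137232653462	0.109007392396	0.79679057195	-0.533305240932
p003	-0.483076513699	-0.40054994153	-0.174112586038	0.685445103018	-0.122501036202	0.377245908659	0.981668102182	-0.530345791965	0.642170368232	0.257872625492	0.0703120138359	0.515166230295	2.14464025301	1.66694616425	2.10389498693	2.28577907021	2.42325503188	1.88285587509
p004	0.381950993199	-0.607416492081	-0.779409117695	0.0204530306343	-0.558980209941	-0.265223292704	0.500131055285	 0.2385141233	-0.492384636954	-0.526023376534	0.0995220270656	0.427150489386	0.556690868962	-0.52064193057	-0.127592906171	0.314116857761	0.254979724364	0.971883261234
p005	0.553399212188	-0.215829489998	0.0808001740918	0.500437296387	0.555723549805	-0.361297487272	0.327677881849	-0.378423356782	-0.0290661491474	0.454840381486	1.29194351691	1.46036898122	0.167008798413	0.45595293092	0.733995840991	0.802005418463	0.0520399899758	-0.240560412831
p006	-0.335894629113	-0.0101345860619	0.0568128887302	-0.535540726774	-0.0739464999245	0.196462146027	-0.1725081457	0.749314380333	0.765595810722	0.0831141723976	-0.384773316928	-0.757824202687	0.0855823470915	-0.0924083138832	0.141582460229	-0.416399365054	-0.48456793545	-1.05614775704
p007	-0.970850215658	-0.949720903161	-0.234180194958	0.884706545371	0.632646801692	0.786091015301	0.89538307589	0.511106828912	-0.233774338807	-0.0818837352578	-0.0773183703847	0.331511297696	1.20585838207	0.442819965741	1.48112084519	-0.411474454045	-1.12634995526	0.498622115627
p008	-1.19904654244	-0.188280827464	-0.285127447283	0.0139074417622	-1.0491743185	0.598144258418	-0.027478232489	-0.761279088572	-0.547630283256	-0.220261548923	0.172437860243	-0.769246086986	-0.281932304207	0.0921330922945	-0.167882894829	0.177470775973	0.0237844784424	-0.464797041764
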