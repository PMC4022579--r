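feature_id	platform	gene_id
m0001	mRNA	g0001
m0002	mRNA	g0002
m0003	mRNA	g0003
m0004	mRNA	g0004
m0005	mRNA	g0005
m0006	mRNA	g0006
m0007	mRNA	g0007
m0008	mRNA	g0008
m0009	mRNA	g0009
m0010	mRNA	g0010
m0011	mRNA	g0011
m0012	mRNA	g0012
m0013	mRNA	g0013
m0014	mRNA	g0014
m0015	mRNA	g0015
m0016	mRNA	g0016
m0017	mRNA	g0017
m0018	mRNA	g0018
m0019	mRNA	g0019
m0020	mRNA	g0020
p001	protein	g0001
p002	protein	g0002
p003	protein	g0003
p004	protein	g0004
p005	protein	g0005
p006	protein	g0006
p007	protein	g0007
p008	protein	g0008
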