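pw001	synthetic pathway	g0015	g0002	g0004	g0003	g0016
pw002	synthetic pathway	g0020	g0015	g0005	g0002
pw003	synthetic pathway	g0007	g0009	g0013	g0002	g0017	g0011
pw_GC	synthetic pathway	g0001	g0002	g0014	g0013	g0007	g0017	g0011	g0003	g0004	g0009	g0005	g0008
pw_NGC	synthetic pathway	g0003	g0004	g0018	g0019	g0012	g0008	g0009	g0010	g0017	g0015	g0001	g0016
pw_NC	synthetic pathway	g0005	g0006	g0010	g0011	g0003	g0001	g0012	g0014	g0020	g0013	g0018	g0004
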