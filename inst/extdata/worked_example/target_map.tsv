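miRNA_id	target_id	evidence	source
mir001	m0001	validated	synthetic-planted
mir001	m0018	validated	synthetic-background
mir002	m0003	validated	synthetic-planted
mir002	m0008	validated	synthetic-background
mir003	m0005	validated	synthetic-planted
mir003	m0010	predicted	synthetic-background
mir005	m0018	predicted	synthetic-background
mir006	m0012	validated	synthetic-background
mir006	m0016	validated	synthetic-background
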