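operon_id	gene_id	position
op001	g0001	1
op001	g0002	2
op002	g0003	1
op002	g0004	2
op002	g0005	3
op002	g0006	4
op002	g0007	5
op003	g0008	1
op003	g0009	2
op003	g0010	3
op003	g0011	4
op004	g0012	1
op004	g0013	2
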