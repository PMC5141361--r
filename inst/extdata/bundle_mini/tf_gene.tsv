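tf_id	target_gene_id	source
g0039	g0037	synthetic
g0040	g0038	synthetic
g0012	g0024	decoy
g0012	g0017	decoy
g0006	g0038	decoy
g0006	g0037	decoy
g0002	g0039	decoy
g0002	g0019	decoy
g0035	g0001	decoy
g0035	g0002	decoy
g0020	g0006	decoy
g0020	g0003	decoy
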