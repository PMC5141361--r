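mirna_id	gene_id	source	assay
mir012	g0007	miRTarBase	reporter
mir011	g0017	miRecords	reporter
mir001	g0005	miRTarBase	reporter
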