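tf_id	mirna_id	source
g0039	mir005	synthetic
g0012	mir012	decoy
g0006	mir011	decoy
g0002	mir005	decoy
g0035	mir001	decoy
g0020	mir009	decoy
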