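mirna_id	gene_id	score
mir001	g0005	0.917627737578005
mir002	g0015	0.836408018833026
mir003	g0025	0.930056018615142
mir004	g0006	0.8747919538524
mir005	g0037	0.822942662285641
mir006	g0040	0.982699170336127
mir006	g0038	0.84007159024477
mir004	g0026	0.564418299589306
mir002	g0005	0.339789531193674
mir012	g0012	0.175671543926001
mir006	g0012	0.863887152867392
mir009	g0032	0.452194288838655
mir003	g0037	0.100573007715866
mir012	g0001	0.0672355315182358
mir009	g0036	0.643858758267015
mir004	g0004	0.41292162775062
mir004	g0023	0.630636527203023
mir001	g0011	0.365503953304142
mir001	g0028	0.228920227382332
mir011	g0036	0.622657295782119
mir011	g0005	0.454626000486314
mir011	g0004	0.669798337155953
mir006	g0026	0.37529893941246
mir007	g0015	0.298579150112346
mir002	g0020	0.578067630995065
mir011	g0035	0.159208110766485
mir005	g0038	0.958675039932132
mir008	g0001	0.836583417840302
mir006	g0017	0.364534525899217
mir009	g0030	0.330554296961054
mir003	g0016	0.8550454901997
mir005	g0027	0.750982345780358
mir012	g0017	0.158338920446113
mir011	g0017	0.146796377142891
mir009	g0025	0.451087150257081
mir002	g0037	0.998757835011929
mir003	g0014	0.308128258213401
mir006	g0027	0.119372789282352
mir010	g0039	0.297442759620026
mir009	g0024	0.807539350353181
mir008	g0018	0.595303905429319
mir005	g0021	0.300867045065388
mir011	g0007	0.631321118213236
mir001	g0006	0.111798670142889
mir009	g0023	0.321378450607881
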