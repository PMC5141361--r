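#pathway	pw1	synthetic pathway pw1
g0001	gene	activation	g0002	gene	1
g0002	gene	activation	g0003	gene	1
g0003	gene	activation	g0004	gene	1
g0004	gene	activation	g0005	gene	1
g0005	gene	inhibition	g0006	gene	1
g0005	gene	activation	g0007	gene	1
g0006	gene	inhibition	g0008	gene	1
g0005	gene	inhibition	g0009	gene	1
g0004	gene	activation	g0010	gene	1
g0009	gene	binding	g0006	gene	0
g0004	gene	binding	g0009	gene	0
#pathway	pw2	synthetic pathway pw2
g0011	gene	inhibition	g0012	gene	1
g0011	gene	inhibition	g0013	gene	1
g0012	gene	inhibition	g0014	gene	1
g0011	gene	activation	g0015	gene	1
g0015	gene	inhibition	g0016	gene	1
g0016	gene	activation	g0017	gene	1
g0011	gene	inhibition	g0018	gene	1
g0011	gene	activation	g0019	gene	1
g0015	gene	activation	g0020	gene	1
g0019	gene	binding	g0012	gene	0
g0017	gene	binding	g0013	gene	0
#pathway	pw3	synthetic pathway pw3
g0021	gene	inhibition	g0022	gene	1
g0021	gene	inhibition	g0023	gene	1
g0021	gene	inhibition	g0024	gene	1
g0022	gene	activation	g0025	gene	1
g0023	gene	activation	g0026	gene	1
g0021	gene	inhibition	g0027	gene	1
g0023	gene	activation	g0028	gene	1
g0023	gene	activation	g0029	gene	1
g0023	gene	inhibition	g0030	gene	1
g0030	gene	binding	g0028	gene	0
g0023	gene	binding	g0022	gene	0
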