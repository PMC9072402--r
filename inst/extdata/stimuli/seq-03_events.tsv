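onset	duration	trial_type
0.012080459787976	0.01	V
0.0565059168683365	0.01	A
0.123057269845158	0.01	V
0.181735592677724	0.01	V
0.30726300180424	0.01	A
0.330931645266246	0.01	A
0.423605915217195	0.01	A
0.926863216683269	0.01	A
0.947222377401777	0.01	V
0.974318913570605	0.01	V
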