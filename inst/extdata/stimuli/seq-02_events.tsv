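onset	duration	trial_type
0.12228968469426	0.01	V
0.138573612894397	0.01	A
0.170743983061984	0.01	A
0.375422185745556	0.01	A
0.396466950981412	0.01	V
0.50269352783449	0.01	V
0.689635559655726	0.01	A
0.711377567804884	0.01	A
0.824424472376704	0.01	V
0.863638127311133	0.01	V
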