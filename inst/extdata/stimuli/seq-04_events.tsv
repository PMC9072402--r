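onset	duration	trial_type
0.116355216144584	0.01	A
0.157246138856281	0.01	A
0.230352111300454	0.01	V
0.30117107599508	0.01	V
0.510055147432722	0.01	A
0.620400994995143	0.01	V
0.677667988399044	0.01	A
0.763349865826312	0.01	V
0.765651921187527	0.01	A
0.835654883277603	0.01	V
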