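onset	duration	trial_type
0.100977031507064	0.01	A
0.125210933638737	0.01	V
0.165200750115328	0.01	V
0.194024867671542	0.01	A
0.705752936538775	0.01	V
0.864655896513723	0.01	V
0.868594452983234	0.01	A
0.90588793015806	0.01	A
0.915962408517953	0.01	V
0.942810519018676	0.01	A
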