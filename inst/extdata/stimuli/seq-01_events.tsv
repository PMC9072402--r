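onset	duration	trial_type
0.104210484654177	0.01	A
0.138248289045878	0.01	A
0.19102981019998	0.01	A
0.225914178041276	0.01	A
0.3073593853903	0.01	A
0.651212414868642	0.01	V
0.707308569415472	0.01	V
0.769314301544801	0.01	V
0.829011930236593	0.01	V
0.918416181076318	0.01	V
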