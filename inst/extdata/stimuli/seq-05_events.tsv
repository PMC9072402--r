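onset	duration	trial_type
0.00428762064082548	0.01	V
0.0885867760423571	0.01	V
0.129501801119186	0.01	V
0.225555893376004	0.01	V
0.53627657657722	0.01	V
0.585789354508743	0.01	A
0.709705190784298	0.01	A
0.80996966538718	0.01	A
0.852670846979599	0.01	A
0.955803106825333	0.01	A
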