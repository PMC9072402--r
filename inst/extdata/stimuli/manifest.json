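{"labels":["seq-01","seq-02","seq-03","seq-04","seq-05","seq-06"],"selection_rho":0.147089432637594,"objective":4.38786528319396e-12,"summaries":{"label":["seq-01","seq-02","seq-03","seq-04","seq-05","seq-06"],"corr_avg":[1.55697886736522e-11,7.36301592150625e-09,8.84319533723022e-09,9.70847853824664e-09,3.05281672051325e-09,1.51100801871318e-08],"lag_avg":[-0.000161699877158251,-6.09587748317971e-05,-2.47770333562017e-05,-5.60984897638051e-05,0.00012899290898486,-1.20403293859612e-05],"corr_z":[-1.51666954140161,0.00292784582206721,0.309058266119449,0.488015970293345,-0.888506718764183,1.60517417793093],"lag_z":[-1.51472216258675,-0.346335179612265,0.0732976691969819,-0.289965994881834,1.85670875816672,0.221016909717151]},"seed":20260925,"n_pool":10000,"rho_max":0.2}
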