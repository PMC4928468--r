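//FITTING PARAMETERS AND INITIAL VALUES
5
0 syn[0].c1 1
1 syn[0].alphab 0.1
2 syn[0].taur 0.2
3 syn[0].taud 8
4 nstim.start 1
//CONSTRAINTS
0.01 50
0.01 0.5
0.05 0.5
3 20
0 4
//DEPENDENCY RULES FOR PARAMETERS NOT FITTED
7
syn[0].w = 1
syn[0].beta = 1
syn[0].alphaf = 1
syn[0].geph = 1
syn[0].phi = 1
syn[0].h = 1
syn[0].h1 = 1
//EXCLUSION RULES
0
//PARAMETERS WARNING (ALL EXCEPT)
0
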