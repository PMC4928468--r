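//FITTING PARAMETERS AND INITIAL VALUES
11
0 syn[0].w 1
1 syn[0].taur 0.2
2 syn[0].taud 8
3 syn[0].beta 1
4 syn[0].alphaf 1
5 syn[0].alphab 0.1
6 syn[0].geph 1
7 syn[0].phi 1
8 syn[0].h 1
9 syn[0].h1 1
10 nstim.start 1
//CONSTRAINTS
0.01 10
0.05 0.5
3 20
0.1 10
0.1 10
0.01 0.5
0.1 10
0.05 1.95
0.1 10
0.1 10
0 4
//DEPENDENCY RULES FOR PARAMETERS NOT FITTED
2
syn[0].nhalf = syn[0].geph/2
syn[0].c1 = 1
//EXCLUSION RULES
1
syn[0].geph < syn[0].nhalf*syn[0].phi
//PARAMETERS WARNING (ALL EXCEPT)
1
nstim.start
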