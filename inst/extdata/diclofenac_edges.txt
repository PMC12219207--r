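# Diclofenac, hydrogen-suppressed molecular graph.
# 19 heavy atoms (C14 Cl2 N O2), 20 bonds.
# 0-5   dichlorophenyl ring (0 bonded to the bridging N)
# 6,7   chlorine atoms on ring carbons 1 and 5
# 8     bridging amine N
# 9-14  phenyl ring of the phenylacetic acid moiety
# 15    methylene carbon, 16 carboxyl carbon, 17-18 carboxyl oxygens
0 1
0 5
0 8
1 2
1 6
2 3
3 4
4 5
5 7
8 9
9 10
9 14
10 11
10 15
11 12
12 13
13 14
15 16
16 17
16 18
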