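time,outcome,post
0,2.0520589072918525,0
1,1.9020309237647717,0
2,2.0339238115019276,0
3,2.021525121505142,0
4,1.9733360384715404,0
5,1.7983910967990542,0
6,1.9864853202543324,0
7,1.9679877736864906,0
8,2.091355444129731,0
9,2.04262090181599,0
10,2.059178529566207,0
11,2.0369566721406382,0
12,2.0978563400593826,0
13,2.107418347557105,0
14,1.8853118553871706,0
15,2.2847001499297033,0
16,2.221640814584997,0
17,2.191756433830789,0
18,2.099528116959974,0
19,2.258974677762582,0
20,2.167132798590976,0
21,2.193531842307416,0
22,2.0807971120228697,0
23,2.3765824761201393,0
24,2.2448206808225444,0
25,2.4408083834641987,0
26,2.433094452723732,0
27,2.27581458372593,0
28,2.344532816177517,0
29,2.4625628986506305,0
30,2.2471033082543754,0
31,2.326639202561255,0
32,2.2945276425236054,0
33,2.363278235943791,0
34,2.358243281282763,0
35,2.4664593749518002,0
36,2.1693492850727867,1
37,2.031822027078263,1
38,2.18972533103574,1
39,2.060509441894196,1
40,2.0382746142376558,1
41,2.2427998774006213,1
42,2.055577821402693,1
43,2.217671410214768,1
44,2.1146341459357942,1
45,2.350814116350375,1
46,2.2911786117850714,1
47,2.190750227713763,1
48,2.321936221871451,1
49,2.2956484435556948,1
50,2.1470101330064377,1
51,2.254379983970698,1
52,2.1929389690756387,1
53,2.341939756579174,1
54,2.2435193545437686,1
55,2.2958577310189043,1
56,2.2063631988554633,1
57,2.2449044701776986,1
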