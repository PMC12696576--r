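item_id,subscale
1,GAD
2,MDD
3,PD
4,SP
5,SAD
6,MDD
7,SP
8,SP
9,SAD
10,OCD
11,MDD
12,SP
13,GAD
14,PD
15,MDD
16,OCD
17,SAD
18,SAD
19,MDD
20,SP
21,MDD
22,GAD
23,OCD
24,PD
25,MDD
26,PD
27,GAD
28,PD
29,MDD
30,SP
31,OCD
32,SP
33,SAD
34,PD
35,GAD
36,PD
37,GAD
38,SP
39,PD
40,MDD
41,PD
42,OCD
43,SP
44,OCD
45,SAD
46,SAD
47,MDD
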