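"var_id","ppm_hi","ppm_lo","assignment","is_glucose"
1,8.6,8.4135,"unassigned (synthetic filler)",FALSE
2,8.4135,8.2271,"unassigned (synthetic filler)",FALSE
3,8.2271,8.0406,"unassigned (synthetic filler)",FALSE
4,8.0406,7.8541,"unassigned (synthetic filler)",FALSE
5,7.8541,7.6676,"unassigned (synthetic filler)",FALSE
6,7.6676,7.4812,"unassigned (synthetic filler)",FALSE
7,7.4812,7.2947,"unassigned (synthetic filler)",FALSE
8,7.2947,7.1082,"unassigned (synthetic filler)",FALSE
9,7.1082,6.9218,"unassigned (synthetic filler)",FALSE
10,6.9218,6.7353,"unassigned (synthetic filler)",FALSE
11,6.7353,6.5488,"unassigned (synthetic filler)",FALSE
12,6.5488,6.3624,"unassigned (synthetic filler)",FALSE
13,6.3624,6.1759,"unassigned (synthetic filler)",FALSE
14,6.1759,5.9894,"unassigned (synthetic filler)",FALSE
15,5.9894,5.8029,"unassigned (synthetic filler)",FALSE
16,5.8029,5.6165,"unassigned (synthetic filler)",FALSE
17,5.6165,5.43,"unassigned (synthetic filler)",FALSE
18,5.43,5.2752,"-HC=CH- in fatty acid chain",FALSE
19,5.2752,5.22,"unassigned (synthetic filler)",TRUE
20,5.22,5.11,"unassigned (synthetic filler)",FALSE
21,5.11,5,"unassigned (synthetic filler)",FALSE
22,4.5,4.455,"unassigned (synthetic filler)",FALSE
23,4.455,4.41,"unassigned (synthetic filler)",FALSE
24,4.41,4.3159,"C1H and C3H in glycerol backbone of triglycerides + OCH2 of choline in sphingomyelin/phosphatidylcholine",FALSE
25,4.3159,4.2842,"unassigned (synthetic filler)",FALSE
26,4.2842,4.2526,"unassigned (synthetic filler)",FALSE
27,4.2526,4.2209,"unassigned (synthetic filler)",FALSE
28,4.2209,4.1893,"unassigned (synthetic filler)",FALSE
29,4.1893,4.1576,"unassigned (synthetic filler)",FALSE
30,4.1576,4.126,"unassigned (synthetic filler)",FALSE
31,4.126,4.0943,"unassigned (synthetic filler)",FALSE
32,4.0943,4.0627,"unassigned (synthetic filler)",FALSE
33,4.0627,4.031,"unassigned (synthetic filler)",FALSE
34,4.031,4.0136,"L-Serine",FALSE
35,4.0136,4.001,"L-Serine",FALSE
36,4.001,3.98,"unassigned (synthetic filler)",TRUE
37,3.98,3.959,"unassigned (synthetic filler)",TRUE
38,3.959,3.833,"D-Glucose",TRUE
39,3.833,3.8143,"unassigned (synthetic filler)",FALSE
40,3.8143,3.7956,"unassigned (synthetic filler)",FALSE
41,3.7956,3.782,"D-Glucose",TRUE
42,3.782,3.755,"D-Glucose",TRUE
43,3.755,3.739,"D-Glucose",TRUE
44,3.739,3.7141,"D-Glucose",TRUE
45,3.7141,3.6937,"unassigned (synthetic filler)",FALSE
46,3.6937,3.6732,"unassigned (synthetic filler)",FALSE
47,3.6732,3.6528,"unassigned (synthetic filler)",FALSE
48,3.6528,3.6323,"unassigned (synthetic filler)",FALSE
49,3.6323,3.6118,"unassigned (synthetic filler)",FALSE
50,3.6118,3.5914,"unassigned (synthetic filler)",FALSE
51,3.5914,3.5649,"D-Glucose",TRUE
52,3.5649,3.551,"D-Glucose",TRUE
53,3.551,3.536,"unassigned (synthetic filler)",FALSE
54,3.536,3.398,"D-Glucose",TRUE
55,3.398,3.3765,"L-Tryptophan",FALSE
56,3.3765,3.3324,"unassigned (synthetic filler)",TRUE
57,3.3324,3.2883,"unassigned (synthetic filler)",TRUE
58,3.2883,3.2441,"unassigned (synthetic filler)",TRUE
59,3.2441,3.2,"unassigned (synthetic filler)",TRUE
60,3.2,3.1697,"unassigned (synthetic filler)",FALSE
61,3.1697,3.1393,"unassigned (synthetic filler)",FALSE
62,3.1393,3.109,"unassigned (synthetic filler)",FALSE
63,3.109,3.086,"L-Cysteine",FALSE
64,3.086,3.0503,"unassigned (synthetic filler)",FALSE
65,3.0503,3.0147,"unassigned (synthetic filler)",FALSE
66,3.0147,2.979,"unassigned (synthetic filler)",FALSE
67,2.979,2.9433,"unassigned (synthetic filler)",FALSE
68,2.9433,2.9077,"unassigned (synthetic filler)",FALSE
69,2.9077,2.872,"unassigned (synthetic filler)",FALSE
70,2.872,2.8363,"unassigned (synthetic filler)",FALSE
71,2.8363,2.8007,"unassigned (synthetic filler)",FALSE
72,2.8007,2.765,"unassigned (synthetic filler)",FALSE
73,2.765,2.7293,"unassigned (synthetic filler)",FALSE
74,2.7293,2.6937,"unassigned (synthetic filler)",FALSE
75,2.6937,2.658,"unassigned (synthetic filler)",FALSE
76,2.658,2.6223,"unassigned (synthetic filler)",FALSE
77,2.6223,2.5867,"unassigned (synthetic filler)",FALSE
78,2.5867,2.551,"unassigned (synthetic filler)",FALSE
79,2.551,2.5153,"unassigned (synthetic filler)",FALSE
80,2.5153,2.4797,"unassigned (synthetic filler)",FALSE
81,2.4797,2.444,"unassigned (synthetic filler)",FALSE
82,2.444,2.4083,"unassigned (synthetic filler)",FALSE
83,2.4083,2.3727,"unassigned (synthetic filler)",FALSE
84,2.3727,2.337,"unassigned (synthetic filler)",FALSE
85,2.337,2.3013,"unassigned (synthetic filler)",FALSE
86,2.3013,2.2657,"unassigned (synthetic filler)",FALSE
87,2.2657,2.23,"unassigned (synthetic filler)",FALSE
88,2.23,2.1943,"unassigned (synthetic filler)",FALSE
89,2.1943,2.1587,"unassigned (synthetic filler)",FALSE
90,2.1587,2.123,"unassigned (synthetic filler)",FALSE
91,2.123,1.972,"-CH2-CH=CH- in fatty acid chain",FALSE
92,1.972,1.8936,"unassigned (synthetic filler)",FALSE
93,1.8936,1.8153,"unassigned (synthetic filler)",FALSE
94,1.8153,1.7369,"unassigned (synthetic filler)",FALSE
95,1.7369,1.6585,"unassigned (synthetic filler)",FALSE
96,1.6585,1.5801,"unassigned (synthetic filler)",FALSE
97,1.5801,1.5017,"unassigned (synthetic filler)",FALSE
98,1.5017,1.4234,"unassigned (synthetic filler)",FALSE
99,1.4234,1.345,"unassigned (synthetic filler)",FALSE
100,1.345,1.2458,"CH3-(CH2)n- in fatty acid chain",FALSE
101,1.2458,1.2147,"unassigned (synthetic filler)",FALSE
102,1.2147,1.1836,"unassigned (synthetic filler)",FALSE
103,1.1836,1.1525,"unassigned (synthetic filler)",FALSE
104,1.1525,1.1214,"unassigned (synthetic filler)",FALSE
105,1.1214,1.0904,"unassigned (synthetic filler)",FALSE
106,1.0904,1.0593,"unassigned (synthetic filler)",FALSE
107,1.0593,1.0282,"unassigned (synthetic filler)",FALSE
108,1.0282,0.9971,"unassigned (synthetic filler)",FALSE
109,0.9971,0.966,"unassigned (synthetic filler)",FALSE
110,0.966,0.8,"CH3-(CH2)n- in fatty acid chain",FALSE
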