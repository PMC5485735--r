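"var_id","mean_case","sd_case","mean_control","sd_control","block","rho"
1,0.7869,0.118,0.7869,0.118,NA,NA
2,0.5549,0.0832,0.5549,0.0832,NA,NA
3,19.7471,2.9621,19.7471,2.9621,NA,NA
4,1.9356,0.2903,1.9356,0.2903,NA,NA
5,40.0806,6.0121,40.0806,6.0121,NA,NA
6,37.7341,5.6601,37.7341,5.6601,NA,NA
7,33.9705,5.0956,33.9705,5.0956,NA,NA
8,4.6607,0.6991,4.6607,0.6991,NA,NA
9,1.0949,0.1642,1.0949,0.1642,NA,NA
10,0.8654,0.1298,0.8654,0.1298,NA,NA
11,1.6542,0.2481,1.6542,0.2481,NA,NA
12,9.3767,1.4065,9.3767,1.4065,NA,NA
13,25.9916,3.8987,25.9916,3.8987,NA,NA
14,14.429,2.1643,14.429,2.1643,NA,NA
15,7.8565,1.1785,7.8565,1.1785,NA,NA
16,7.052,1.0578,7.052,1.0578,NA,NA
17,4.8021,0.7203,4.8021,0.7203,NA,NA
18,21.95,3.63,30.95,4,"lipid",0.6
19,1.2825,0.1924,1.2825,0.1924,"glucose",0.8
20,36.6619,5.4993,36.6619,5.4993,NA,NA
21,5.5687,0.8353,5.5687,0.8353,NA,NA
22,4.6062,0.6909,4.6062,0.6909,NA,NA
23,8.9665,1.345,8.9665,1.345,NA,NA
24,3.28,1.16,5.09,1.16,"lipid",0.6
25,0.6828,0.1024,0.6828,0.1024,NA,NA
26,3.5418,0.5313,3.5418,0.5313,NA,NA
27,11.4887,1.7233,11.4887,1.7233,NA,NA
28,15.5407,2.3311,15.5407,2.3311,NA,NA
29,4.8187,0.7228,4.8187,0.7228,NA,NA
30,1.1084,0.1663,1.1084,0.1663,NA,NA
31,37.4994,5.6249,37.4994,5.6249,NA,NA
32,14.5518,2.1828,14.5518,2.1828,NA,NA
33,3.9937,0.5991,3.9937,0.5991,NA,NA
34,0.7,0.26,1.21,0.22,NA,NA
35,0.84,0.28,1.29,0.23,NA,NA
36,36.3351,5.4503,36.3351,5.4503,"glucose",0.8
37,0.5471,0.0821,0.5471,0.0821,"glucose",0.8
38,91.99,16.9,64.44,6.58,"glucose",0.8
39,43.4985,6.5248,43.4985,6.5248,NA,NA
40,0.5913,0.0887,0.5913,0.0887,NA,NA
41,7.62,0.6,6.18,0.6,"glucose",0.8
42,30.58,5.63,20.56,1.95,"glucose",0.8
43,17.92,3.83,11.85,1.35,"glucose",0.8
44,17.76,3.24,13.05,1.49,"glucose",0.8
45,1.0867,0.163,1.0867,0.163,NA,NA
46,0.5644,0.0847,0.5644,0.0847,NA,NA
47,11.5033,1.7255,11.5033,1.7255,NA,NA
48,2.3014,0.3452,2.3014,0.3452,NA,NA
49,1.9589,0.2938,1.9589,0.2938,NA,NA
50,2.274,0.3411,2.274,0.3411,NA,NA
51,14.45,2.19,10.2,1.06,"glucose",0.8
52,5.84,1.1,3.65,0.5,"glucose",0.8
53,0.5738,0.0861,0.5738,0.0861,NA,NA
54,116.37,30.4,69.27,8.54,"glucose",0.8
55,0.7,0.32,1.94,0.41,NA,NA
56,31.335,4.7002,31.335,4.7002,"glucose",0.8
57,3.748,0.5622,3.748,0.5622,"glucose",0.8
58,2.697,0.4045,2.697,0.4045,"glucose",0.8
59,0.5429,0.0814,0.5429,0.0814,"glucose",0.8
60,0.6721,0.1008,0.6721,0.1008,NA,NA
61,13.2699,1.9905,13.2699,1.9905,NA,NA
62,0.7202,0.108,0.7202,0.108,NA,NA
63,2.28,0.47,3.05,0.39,NA,NA
64,12.4342,1.8651,12.4342,1.8651,NA,NA
65,11.4467,1.717,11.4467,1.717,NA,NA
66,9.3466,1.402,9.3466,1.402,NA,NA
67,0.7869,0.118,0.7869,0.118,NA,NA
68,3.1606,0.4741,3.1606,0.4741,NA,NA
69,18.2013,2.7302,18.2013,2.7302,NA,NA
70,8.8962,1.3344,8.8962,1.3344,NA,NA
71,4.3046,0.6457,4.3046,0.6457,NA,NA
72,1.7901,0.2685,1.7901,0.2685,NA,NA
73,19.9224,2.9884,19.9224,2.9884,NA,NA
74,2.2053,0.3308,2.2053,0.3308,NA,NA
75,1.1634,0.1745,1.1634,0.1745,NA,NA
76,1.0922,0.1638,1.0922,0.1638,NA,NA
77,4.4379,0.6657,4.4379,0.6657,NA,NA
78,8.3873,1.2581,8.3873,1.2581,NA,NA
79,0.7201,0.108,0.7201,0.108,NA,NA
80,0.7669,0.115,0.7669,0.115,NA,NA
81,12.9706,1.9456,12.9706,1.9456,NA,NA
82,2.2899,0.3435,2.2899,0.3435,NA,NA
83,6.2094,0.9314,6.2094,0.9314,NA,NA
84,14.157,2.1236,14.157,2.1236,NA,NA
85,1.2285,0.1843,1.2285,0.1843,NA,NA
86,1.8669,0.28,1.8669,0.28,NA,NA
87,9.1894,1.3784,9.1894,1.3784,NA,NA
88,37.0541,5.5581,37.0541,5.5581,NA,NA
89,1.4476,0.2171,1.4476,0.2171,NA,NA
90,4.3207,0.6481,4.3207,0.6481,NA,NA
91,53.13,7.19,64.03,3.76,"lipid",0.6
92,1.0447,0.1567,1.0447,0.1567,NA,NA
93,46.5074,6.9761,46.5074,6.9761,NA,NA
94,0.566,0.0849,0.566,0.0849,NA,NA
95,0.6822,0.1023,0.6822,0.1023,NA,NA
96,11.0075,1.6511,11.0075,1.6511,NA,NA
97,1.2279,0.1842,1.2279,0.1842,NA,NA
98,3.8447,0.5767,3.8447,0.5767,NA,NA
99,7.8507,1.1776,7.8507,1.1776,NA,NA
100,117.69,17.62,155.4,22.01,"lipid",0.6
101,6.2652,0.9398,6.2652,0.9398,NA,NA
102,0.5033,0.0755,0.5033,0.0755,NA,NA
103,2.651,0.3976,2.651,0.3976,NA,NA
104,0.7893,0.1184,0.7893,0.1184,NA,NA
105,2.1711,0.3257,2.1711,0.3257,NA,NA
106,25.654,3.8481,25.654,3.8481,NA,NA
107,0.532,0.0798,0.532,0.0798,NA,NA
108,9.8457,1.4769,9.8457,1.4769,NA,NA
109,47.4776,7.1216,47.4776,7.1216,NA,NA
110,89.1,14.79,111.75,7.83,"lipid",0.6
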