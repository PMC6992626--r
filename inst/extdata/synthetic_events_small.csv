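event_id,tof,peak_green,width_green,int_green,int_red,int_yellow
17,6055.772,500,5000,1557655.793,100,100
49,9682.611,500,5000,3348842.209,100,100
37,1449.226,500,5000,102551.622,100,100
56,5878.304,40,5000,100,100,100
45,5868.261,500,5000,1302827.741,100,100
19,11089.087,500,5000,3890611.94,100,100
60,6799.378,40,5000,100,100,100
28,6451.983,500,5000,1799043.18,100,100
13,6104.616,500,5000,1457109.285,100,100
39,806.058,500,5000,32773.179,100,100
23,8369.921,500,5000,2441954.13,100,100
26,7467.69,500,5000,1897245.527,100,100
6,6624.097,500,5000,1396737.268,100,100
50,7051.681,500,5000,1386383.942,100,100
9,6193.978,500,5000,1501931.944,100,100
30,4435.417,500,5000,868621.952,100,100
12,8602.907,500,5000,2652225.464,100,100
25,1685.516,500,5000,142173.422,100,100
55,100,500,5000,100,100,100
4,11002.323,500,5000,3795969.613,100,100
48,11162.478,500,5000,3543244.319,100,100
47,898.029,500,5000,42498.367,100,100
21,4316.951,500,5000,798021.726,100,100
59,20000,500,5000,100,100,100
40,8314.432,500,5000,1977328.217,100,100
2,5453.164,500,5000,981723.562,100,100
58,6782.518,500,5000,100,10,100
42,6588.562,500,5000,1462206.815,100,100
14,1701.261,500,5000,165431.869,100,100
53,6543.565,500,5000,1773667.222,100,100
57,7032.607,500,1000,100,100,100
7,6986.301,500,5000,1743736.2,100,100
43,11912.405,500,5000,4446503.778,100,100
34,9610.296,500,5000,2865563.341,100,100
22,617.954,500,5000,19988.628,100,100
3,8006.153,500,5000,1962642.168,100,100
24,5086.197,500,5000,948894.141,100,100
1,9689.974,500,5000,2469063.357,100,100
32,7603.951,500,5000,2067423.945,100,100
33,11844.066,500,5000,3588343.927,100,100
10,7870.524,500,5000,2014820.564,100,100
15,7451.76,500,5000,1928829.833,100,100
51,7808.145,500,5000,2204303.977,100,100
18,12995.845,500,5000,4079831.807,100,100
11,2169.844,500,5000,249417.351,100,100
35,6320.208,500,5000,1377188.499,100,100
41,5912.032,500,5000,1388625.487,100,100
27,10935.465,500,5000,3419234.048,100,100
44,8919.608,500,5000,2787935.296,100,100
46,8276.869,500,5000,2346315.183,100,100
29,6386.35,500,5000,1540448.625,100,100
16,7410.893,500,5000,1908083.133,100,100
52,3871.519,500,5000,657810.573,100,100
31,8841.969,500,5000,2891379.174,100,100
36,11753.714,500,5000,4653981.751,100,100
5,11166.14,500,5000,3320359.426,100,100
20,7404.301,500,5000,1733037.777,100,100
8,4883.498,500,5000,791715,100,100
54,6338.292,500,5000,1596985.835,100,100
38,6765.586,500,5000,1652390.313,100,100
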