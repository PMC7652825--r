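volunteer,visual_score,dchi_mean,cnr_mean,dchi_peak,cnr_peak,dchi_ap,cnr_ap,dchi_ml,cnr_ml
1,2,-0.0054,-0.5970,0.0390,4.4270,0.0177,2.0172,0.0089,1.0268
2,1.3333,0.0061,0.6922,0.0298,2.8971,0.0120,1.0502,-0.0047,-0.4432
3,3,0.0248,2.4265,0.0431,4.2255,0.0270,2.6422,-0.0030,-0.2941
4,1,0.0042,0.2802,0.0250,2.6418,0.0160,1.6252,-0.0044,-0.4613
5,1,0.0104,1.7250,0.0268,3.1327,0.0124,0.9529,-0.0063,-1.0417
6,2.3333,0.0308,3.3115,0.0560,5.9889,0.0396,4.2264,0.0068,0.6899
7,2.3333,0.0026,0.3791,0.0422,5.2199,0.0240,2.9950,0.0156,1.8958
8,1.3333,0.0134,1.1419,0.0409,3.5007,0.0285,2.4614,0.0177,1.4945
9,2.3333,0.0281,2.7496,0.0342,3.3439,0.0208,2.0056,-0.0143,1.9955
10,2.6667,0.0147,1.2500,0.0517,4.3121,0.0386,3.2353,0.0038,-1.4020
11,2.3333,0.0272,2.1683,0.0411,3.3306,0.0244,2.0340,-0.0117,0.3265
12,2.6667,0.0108,1.3612,0.0388,4.3524,0.0208,2.4817,-0.0098,-1.0209
13,1,-0.0057,-0.4408,0.0323,2.0910,0.0098,0.5016,-0.0106,-1.0580
14,3,0.0298,2.0105,0.0727,5.3526,0.0483,3.6371,-0.0044,-0.8327
15,3,0.0037,0.2743,0.0591,4.4791,0.0309,2.3371,0.0171,-0.1669
16,3,0.0637,7.6586,0.0829,9.7916,0.0595,7.0944,-0.0160,1.2800
17,2.6667,-0.0041,-0.3841,0.0435,4.1440,0.0242,2.3042,0.0153,-2.1660
18,3,0.0142,1.4935,0.0555,5.8546,0.0376,3.8548,0.0017,1.4562
19,1,-0.0090,-0.8513,0.0358,3.3922,-0.0026,-0.2382,0.0211,0.1965
20,2,0.0125,0.9157,0.0413,3.7549,0.0174,1.5999,0.0089,0.9814
21,3,0.0251,2.7099,0.0575,6.2198,0.0350,3.7820,0.0120,1.3006
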