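# Daily rainfall (mm), 1-30 June 2022, Chiang Rai and Chiang Mai provinces,
# Thailand. Source: Thai Meteorological Department (public daily reports).
# "-" marks an unrecorded day (treated as a missing record).
chiang_rai,chiang_mai
0.0,0.0
0.4,0.0
0.5,0.0
0.0,0.0
0.0,41.9
0.0,0.4
0.1,0.0
0.0,0.0
0.2,0.1
0.0,0.0
0.0,0.0
0.0,0.0
0.0,0.0
3.3,0.0
21.0,1.3
7.9,0.0
0.2,0.2
0.0,-
-,-
2.5,0.0
0.0,0.0
0.0,0.0
47.5,23.1
0.5,0.0
0.0,0.1
10.4,-
0.0,0.0
0.0,-
9.0,5.4
-,8.7
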