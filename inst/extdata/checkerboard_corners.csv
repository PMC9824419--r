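point,u_obs,v_obs,u_est,v_est
1,435,122,434,121
2,435,393,437,394
3,437,667,436,666
4,1097,667,1100,668
5,1755,667,1753,666
6,1755,429,1757,430
7,1752,119,1751,119
8,1092,122,1094,122
9,962,312,961,311
10,964,484,963,483
11,1251,479,1250,478
12,1246,312,1245,311
13,1152,395,1152,397
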