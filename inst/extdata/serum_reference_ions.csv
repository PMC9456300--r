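row_id,mz,z,rt,intensity
1,855.3,1,8.81,1
2,969.35,1,8.98,1
3,1127.42,1,9.21,1
4,731.31,2,9.44,1
4,1463.62,1,9.44,1
5,653.26,2,9.46,1
5,1307.52,1,9.46,1
6,1105.47,1,9.48,1
7,595.74,2,9.51,1
7,1192.5,1,9.51,1
8,673.8,2,9.54,1
8,1348.6,1,9.54,1
9,601.77,2,9.63,1
9,1204.55,1,9.63,1
10,806.81,2,9.97,1
10,1614.62,1,9.97,1
11,771.29,2,10,1
11,1543.59,1,10,1
12,728.76,2,10.04,1
12,1458.52,1,10.04,1
13,661.24,2,10.28,1
13,1323.5,1,10.28,1
14,617.73,2,10.45,1
14,1236.46,1,10.45,1
15,748.79,2,10.45,1
15,1498.58,1,10.45,1
16,696.76,2,10.6,1
16,1394.54,1,10.6,1
17,697.25,2,10.83,1
17,1395.51,1,10.83,1
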