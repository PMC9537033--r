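id,n_seeds,improved_rw,rw_with_seeds,rw_without_seeds,time_s
1,276,0.9193,0.7727,0.7452,1.2500
2,235,0.8903,0.9291,0.8434,1.2650
3,297,0.9203,0.8024,0.7634,1.2521
4,349,0.8231,0.7054,0.6901,1.3190
5,216,0.9321,0.9193,0.9025,1.4760
6,197,0.8929,0.7544,0.7146,1.3440
7,302,0.8340,0.7053,0.7568,1.3280
8,189,0.8853,0.7619,0.7023,1.6310
9,243,0.8727,0.8820,0.7823,1.3440
10,379,0.9341,0.8319,0.8726,1.3260
11,197,0.8290,0.8920,0.8340,1.6950
12,264,0.8631,0.8631,0.7920,1.2810
13,375,0.8498,0.8012,0.7034,1.3520
14,294,0.8920,0.8290,0.8401,1.2970
15,176,0.9352,0.8031,0.7432,1.4230
16,276,0.8860,0.8460,0.6931,1.4690
17,307,0.7964,0.7254,0.7350,1.3130
18,238,0.9453,0.8015,0.7031,1.4220
19,398,0.8624,0.8106,0.8326,1.2190
20,289,0.9540,0.8342,0.7920,1.2820
21,208,0.7786,0.7326,0.7021,1.3550
22,178,0.7695,0.7690,0.7431,1.3130
23,267,0.8442,0.6524,0.6014,1.2340
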