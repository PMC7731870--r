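facility_id,pre_rate,during_rate,decline10,decline20,don_turnover,support,low_baseline,chess
1,3.146,1.251,1,1,0,1,0,1
2,3.270,1.410,1,1,1,1,0,1
3,4.372,1.711,1,1,1,1,0,1
4,1.922,1.262,1,1,0,1,0,1
5,2.670,1.960,1,1,0,1,0,0
6,2.417,1.219,1,1,1,1,0,0
7,1.530,1.196,1,1,0,1,0,1
8,1.690,1.224,1,1,1,1,0,0
9,1.079,0.803,1,1,1,1,1,1
10,2.908,1.830,1,1,0,0,0,0
11,2.214,1.443,1,1,1,0,0,1
12,1.537,1.155,1,1,1,0,0,1
13,1.734,1.202,1,1,0,0,0,1
14,1.331,1.147,1,0,1,0,1,0
15,3.422,3.053,1,0,1,0,0,0
16,0.963,1.137,0,0,0,1,1,1
17,0.749,0.831,0,0,0,1,1,0
18,0.906,1.528,0,0,0,1,1,1
19,1.823,2.335,0,0,0,0,0,1
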