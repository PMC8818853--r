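ss_amount,ll_amount,ll_delay_days,k_indiff,k_rank,magnitude
34,35,186,0.00016,1,small
28,30,179,0.00040,2,small
22,25,136,0.0010,3,small
25,30,80,0.0025,4,small
19,25,53,0.0060,5,small
24,35,29,0.016,6,small
14,25,19,0.041,7,small
15,35,13,0.10,8,small
11,30,7,0.25,9,small
78,80,162,0.00016,1,large
80,85,157,0.00040,2,large
67,75,119,0.0010,3,large
69,85,91,0.0025,4,large
55,75,61,0.0060,5,large
54,80,30,0.016,6,large
41,75,20,0.041,7,large
33,80,14,0.10,8,large
31,85,7,0.25,9,large
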