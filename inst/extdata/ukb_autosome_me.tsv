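autosome	n_markers	me_c	me_w_c
1	41805	10333.95	5531.40
2	42087	10131.61	5410.58
3	35488	8377.99	4557.51
4	33248	8168.11	4567.46
5	31855	7772.11	4200.29
6	36643	1217.21	522.52
7	28868	6996.85	3882.00
8	27244	5878.64	2941.71
9	23120	6172.40	3423.64
10	26242	5978.38	3607.96
11	26119	4978.77	2835.29
12	25041	6204.85	3385.99
13	18065	4988.62	2802.15
14	17040	4492.59	2458.88
15	16555	3911.11	2174.81
16	18570	4448.96	2461.84
17	17140	3868.71	2040.32
18	15837	4561.48	2549.61
19	13998	3151.14	1816.42
20	13997	3800.48	2080.39
21	7949	2223.92	1231.52
22	8549	2114.08	1240.90
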