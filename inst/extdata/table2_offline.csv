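subject,paradigm,sr,acc,itr
1,RCP,13.46,100.00,69.61
2,RCP,13.32,95,61.61
3,RCP,14.769,100.00,76.35
4,RCP,11.12,100.00,57.51
5,RCP,12.938,95,59.86
6,RCP,14.90,95,68.97
7,RCP,14.747,100.00,76.24
8,RCP,13.278,100.00,68.64
9,RCP,14.307,95,66.20
10,RCP,12.55,100.00,64.87
1,CBP,13.87,95,64.19
2,CBP,12.94,100.00,66.89
3,CBP,13.75,100.00,71.10
4,CBP,9.80,100.00,50.64
5,CBP,13.52,95,62.56
6,CBP,14.44,100.00,74.63
7,CBP,14.24,100.00,73.63
8,CBP,12.70,100.00,65.65
9,CBP,12.57,100.00,64.96
10,CBP,14.63,95,67.71
1,COMB,13.91,100.00,71.93
2,COMB,15.07,100.00,77.91
3,COMB,15.71,95,72.70
4,COMB,13.79,100.00,71.31
5,COMB,12.97,100.00,67.07
6,COMB,14.55,100.00,75.20
7,COMB,13.87,100.00,71.72
8,COMB,13.93,100.00,72.03
9,COMB,14.14,95,65.42
10,COMB,13.56,100.00,70.10
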