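subject,paradigm,sr,acc,itr
1,RCP,14.65,100.00,75.73
2,RCP,16.46,100.00,85.11
3,RCP,16.79,100.00,86.82
4,RCP,12.38,98.59,61.77
5,RCP,15.05,81.25,52.87
6,RCP,15.34,100.00,79.3
7,RCP,15.35,100.00,79.35
8,RCP,13.39,95.95,63.17
9,RCP,13.71,100.00,70.88
10,RCP,12.79,100.00,66.13
1,CBP,15.08,100.00,77.94
2,CBP,16.11,100.00,83.3
3,CBP,15.43,100.00,79.76
4,CBP,11.48,100.00,59.36
5,CBP,13.89,100.00,71.79
6,CBP,13.63,100.00,70.48
7,CBP,13.19,100.00,68.21
8,CBP,12.58,100.00,65.06
9,CBP,14.51,100.00,75.02
10,CBP,12.18,100.00,62.99
1,COMB,15.86,97.27,76.91
2,COMB,17.14,100.00,88.6
3,COMB,16.61,100.00,85.89
4,COMB,10.63,94.74,48.93
5,COMB,12.41,82.50,44.71
6,COMB,14.72,100.00,76.11
7,COMB,12.77,98.57,63.7
8,COMB,14.72,76.92,47.2
9,COMB,14.79,90.67,62.78
10,COMB,10.01,97.67,48.97
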