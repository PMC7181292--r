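subject,scenario,spr_rms_mv,hr_bpm,sdnn_ms,lf_ms2,lf_hf
1,no_traffic,0.271,96.9,25.17,333,6.11
2,no_traffic,0.651,97.5,41.62,455,5.01
3,no_traffic,0.307,74.3,44.71,937,4.69
4,no_traffic,0.571,75.9,66.21,831,4.71
5,no_traffic,1.5,71.4,52.31,1129,3.74
6,no_traffic,0.092,73.9,50.81,442,2.25
7,no_traffic,0.124,67.8,45.51,770,3.75
8,no_traffic,0.326,80.9,34.71,631,3.57
9,no_traffic,0.191,79.9,42.31,798,2.24
10,no_traffic,0.186,78.4,37.42,813,2.07
1,traffic,0.379,96.1,32.51,502,12.2
2,traffic,0.773,97.6,39.62,405,5.61
3,traffic,0.434,75.8,52.73,918,3.14
4,traffic,0.653,75.4,63.84,1499,8.64
5,traffic,1.6,72.1,57.82,1352,4.17
6,traffic,0.299,76.3,114.3,586,3.04
7,traffic,0.921,71.9,52.61,861,2.55
8,traffic,0.354,82.8,31.62,391,6.55
9,traffic,0.223,84.7,36.42,830,4.62
10,traffic,0.241,79.6,41.85,783,3.48
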