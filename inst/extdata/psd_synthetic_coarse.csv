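size_um,volume_fraction,replicate
7.5,0.002403,1
9.627,0.004319,1
12.357,0.007371,1
15.861,0.011947,1
20.358,0.018393,1
26.131,0.026896,1
33.541,0.037356,1
43.052,0.049279,1
55.26,0.061743,1
70.931,0.073477,1
91.044,0.083051,1
116.862,0.08916,1
150,0.090913,1
192.535,0.088046,1
247.132,0.08099,1
317.211,0.070758,1
407.163,0.058716,1
522.621,0.046277,1
670.82,0.034643,1
861.044,0.024631,1
1105.209,0.016634,1
1418.612,0.010669,1
1820.887,0.0065,1
2337.233,0.003761,1
3000,0.002067,1
7.5,0.00223,2
9.627,0.004032,2
12.357,0.006924,2
15.861,0.011295,2
20.358,0.017498,2
26.131,0.025748,2
33.541,0.035987,2
43.052,0.047772,2
55.26,0.060233,2
70.931,0.072132,2
91.044,0.082044,2
116.862,0.088634,2
150,0.090946,2
192.535,0.088634,2
247.132,0.082044,2
317.211,0.072132,2
407.163,0.060233,2
522.621,0.047772,2
670.82,0.035987,2
861.044,0.025748,2
1105.209,0.017498,2
1418.612,0.011294,2
1820.887,0.006924,2
2337.233,0.004032,2
3000,0.00223,2
7.5,0.002022,3
9.627,0.003686,3
12.357,0.006382,3
15.861,0.010495,3
20.358,0.016391,3
26.131,0.024315,3
33.541,0.034261,3
43.052,0.04585,3
55.26,0.058279,3
70.931,0.070359,3
91.044,0.080678,3
116.862,0.087866,3
150,0.090891,3
192.535,0.0893,3
247.132,0.083332,3
317.211,0.073859,3
407.163,0.062176,3
522.621,0.049714,3
670.82,0.037754,3
861.044,0.027232,3
1105.209,0.018657,3
1418.612,0.01214,3
1820.887,0.007503,3
2337.233,0.004404,3
3000,0.002455,3
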