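size_um,volume_fraction,replicate
1.9,0.001192,1
2.439,0.00243,1
3.13,0.004649,1
4.018,0.008364,1
5.157,0.014133,1
6.62,0.022446,1
8.497,0.033485,1
10.907,0.046941,1
13.999,0.06182,1
17.969,0.076503,1
23.065,0.088953,1
29.605,0.097178,1
38,0.099749,1
48.776,0.096202,1
62.607,0.087176,1
80.36,0.074223,1
103.148,0.059377,1
132.397,0.04463,1
169.941,0.031519,1
218.131,0.020915,1
279.986,0.01304,1
359.382,0.007639,1
461.291,0.004204,1
592.099,0.002174,1
760,0.001056,1
1.9,0.001123,2
2.439,0.002299,2
3.13,0.004421,2
4.018,0.007995,2
5.157,0.013577,2
6.62,0.021671,2
8.497,0.032494,2
10.907,0.045781,2
13.999,0.060598,2
17.969,0.07537,2
23.065,0.088078,2
29.605,0.096708,2
38,0.099769,2
48.776,0.096708,2
62.607,0.088077,2
80.36,0.07537,2
103.148,0.060599,2
132.397,0.045779,2
169.941,0.032494,2
218.131,0.021671,2
279.986,0.013579,2
359.382,0.007995,2
461.291,0.004423,2
592.099,0.002299,2
760,0.001123,2
1.9,0.001058,3
2.439,0.002177,3
3.13,0.004207,3
4.018,0.007645,3
5.157,0.013048,3
6.62,0.02093,3
8.497,0.031538,3
10.907,0.044655,3
13.999,0.0594,3
17.969,0.074246,3
23.065,0.087195,3
29.605,0.096213,3
38,0.09975,3
48.776,0.097168,3
62.607,0.088935,3
80.36,0.076481,3
103.148,0.061797,3
132.397,0.046916,3
169.941,0.033466,3
218.131,0.022429,3
279.986,0.014124,3
359.382,0.008357,3
461.291,0.004646,3
592.099,0.002427,3
760,0.001191,3
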