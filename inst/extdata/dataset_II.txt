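# Benchmark lifetime dataset II (n = 50)
0.008, 0.017, 0.058, 0.061, 0.084, 0.090, 0.134, 0.238, 0.245, 0.353
0.374, 0.480, 0.495, 0.535, 0.564, 0.681, 0.686, 0.688, 0.921, 0.959
1.022, 1.092, 1.260, 1.284, 1.295, 1.373, 1.395, 1.414, 1.760, 1.858
1.892, 1.921, 1.926, 1.933, 2.135, 2.169, 2.301, 2.320, 2.405, 2.506
2.598, 2.808, 2.971, 3.087, 3.492, 3.669, 3.926, 4.446, 5.119, 8.596
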