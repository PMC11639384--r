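# Benchmark dataset III: failure stresses (n = 23, contains ties)
17.88, 28.92, 33.0, 41.52, 42.12, 45.6, 48.8, 51.84, 51.96, 54.12
55.56, 67.8, 68.44, 68.88, 84.12, 93.12, 98.64, 105.12, 105.84, 105.84
127.92, 128.04, 173.4
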