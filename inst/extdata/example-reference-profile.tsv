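depth_cm dose
0.0 2.01
2.0 2.05
4.0 2.08
8.0 2.06
12.0 1.98
16.0 1.86
20.0 1.66
24.0 1.38
28.0 1.02
30.0 0.80
32.0 0.55
34.0 0.30
36.0 0.12
38.0 0.03
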