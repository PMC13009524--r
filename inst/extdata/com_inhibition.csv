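# COM dissolution rates vs coffee-extract inhibitor concentration at
# sigma = 0.20, 37.0 C, I = 0.15 mol dm^-3, pH 6.0, 10 mg seed.
# Row with inhibitor_molar = 0 is the control rate R0. Only primary columns
# are stored; derived columns (1/C, theta, C/theta, R0/(R0-Ri)) are always
# recomputed from these because the published derived table contains a
# transcription error (1/C = 2.300 at C = 3.0e-6 is arithmetically
# impossible; 1/C = 3.333e5 dm^3 mol^-1).
inhibitor_molar,rate
0,3.027e-6
2.000e-6,2.895e-6
2.220e-6,2.879e-6
2.500e-6,2.863e-6
3.000e-6,2.828e-6
4.000e-6,2.786e-6
5.000e-6,2.712e-6
6.000e-6,2.607e-6
7.000e-6,2.601e-6
8.000e-6,2.554e-6
9.000e-6,2.486e-6
10.000e-6,2.466e-6
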