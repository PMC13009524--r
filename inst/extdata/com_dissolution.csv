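# Constant-composition dissolution of COM seed crystals, 1:1 Ca:oxalate,
# 37.0 C, pH 6.0, I = 0.15 mol dm^-3. Two series: control (no additive) and
# additive (coffee extract). Rates in mol m^-2 min^-1 (printed "mol m^-1
# min^-1" is interpreted as area-normalized; numbers used verbatim).
# sigma is the printed 2-figure value; it is recomputed from t_ca_molar and
# H0^1/2 = 1.994e-4 wherever the analysis needs full precision.
t_ca_molar,sigma,rate,seed_mg,rpm,inhibitor_molar,label
1.791e-4,0.10,1.023e-6,10,300,0,control
1.751e-4,0.12,1.271e-6,10,300,0,control
1.692e-4,0.15,2.301e-6,10,300,0,control
1.652e-4,0.17,2.606e-6,10,300,0,control
1.592e-4,0.20,3.027e-6,10,300,0,control
1.493e-4,0.25,4.581e-6,10,300,0,control
1.453e-4,0.27,5.520e-6,10,300,0,control
1.433e-4,0.28,5.955e-6,10,300,0,control
1.791e-4,0.10,0.832e-6,10,300,1e-7,additive
1.751e-4,0.12,1.095e-6,10,300,1e-7,additive
1.692e-4,0.15,1.712e-6,10,300,1e-7,additive
1.652e-4,0.17,2.071e-6,10,300,1e-7,additive
1.592e-4,0.20,2.652e-6,10,300,1e-7,additive
1.493e-4,0.25,3.985e-6,10,300,1e-7,additive
1.453e-4,0.27,4.814e-6,10,300,1e-7,additive
1.433e-4,0.28,4.999e-6,10,300,1e-7,additive
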