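group,temperature_K,k,intercept,r_squared
EG,277.15,0.00138,0.084,0.94736
EG,298.15,0.00632,0.0938,0.9743
EG,310.15,0.06356,0.07782,0.97667
CG,277.15,0.00205,0.08364,0.98298
CG,298.15,0.01005,0.08128,0.97781
CG,310.15,0.07905,0.07322,0.98496
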