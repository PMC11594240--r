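group,temperature_K,actual,actual_unit,predicted,predicted_unit
EG,277.15,50,d,55,d
EG,298.15,2.5,d,2.7,d
EG,310.15,26,h,28,h
CG,277.15,36,d,38,d
CG,298.15,1.4,d,1.5,d
CG,310.15,19,h,20,h
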