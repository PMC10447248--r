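group,ee_warm,ee_cold,scv_warm,scv_cold,sternal_warm,sternal_cold
normal_weight,1477,1635,35.4,34.4,34.3,32.7
obese,1897,1984,34.7,33.4,33.6,31.0
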