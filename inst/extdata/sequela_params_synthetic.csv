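cause,phase,duration_years,disability_weight
default,diagnosis_treatment,0.25,0.288
default,remission,,0.049
default,metastatic,0.333333333333333,0.451
default,terminal,0.0833333333333333,0.54
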