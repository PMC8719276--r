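cause,procedure,proportion,disability_weight
bladder,urinary_diversion,0.1,0.142
breast,mastectomy,0.25,0.036
colorectal,stoma,0.15,0.095
larynx,laryngectomy,0.3,0.051
prostate,prostatectomy_sequelae,0.2,0.017
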