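kvp,transmission,prefilter_al_mm
70,0.683,2.5
81,0.687,2.5
90,0.695,2.5
96,0.701,2.5
102,0.709,2.5
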