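layers,real_thickness_mm,kvp,effective_thickness_mm
1,0.43,80,0.107
1,0.43,90,0.105
1,0.43,100,0.104
2,0.86,80,0.208
2,0.86,90,0.204
2,0.86,100,0.203
3,1.29,80,0.306
3,1.29,90,0.309
3,1.29,100,0.298
4,1.73,80,0.399
4,1.73,90,0.391
4,1.73,100,0.391
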