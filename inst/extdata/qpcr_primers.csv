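gene,direction,sequence
gapdh,fwd,CATGGCCTTCCGTGTTCCTA
gapdh,rev,GCGGCACGTCAGATCCA
rhoA,fwd,GGGCGTGGATGCGTTCT
rhoA,rev,ACGCGCGCACACTCTCA
rhoQ,fwd,GCGCGTCCTGTGGGATT
rhoQ,rev,GCTCCAAGCGGACATCAGTT
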