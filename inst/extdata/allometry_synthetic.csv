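taxon_group,a,b
Coleoptera,0.05,2.6
Hemiptera,0.05,2.6
Araneae-hunting,0.05,2.6
Araneae-web,0.05,2.6
Hymenoptera,0.05,2.6
Orthoptera,0.05,2.6
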