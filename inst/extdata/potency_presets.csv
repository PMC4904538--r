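fiber_type,scenario,relative_potency
commercial_chrysotile,lifetime,1
commercial_chrysotile,occupational,1
commercial_chrysotile,example,1
amosite,lifetime,100
amosite,occupational,35
crocidolite,lifetime,500
crocidolite,occupational,200
generic_amphibole,example,50
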