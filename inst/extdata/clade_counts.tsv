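# Distribution of analyzed species and sequences across fungal clades
phylum	clade	species	pp1	ppz
Ascomycota	Saccharomycotina	15	15	18
Ascomycota	Pezizomycotina	13	13	13
Ascomycota	Taphrinomycotina	7	11	7
Basidiomycota	Agaricomycotina	10	11	10
Basidiomycota	Wallemiomycetes_Ustilagomycotina_Pucciniomycotina	5	5	5
Monokaryotic	Zygomycota_Chytridiomycota_Cryptomycota	7	9	14
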