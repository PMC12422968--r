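# Methyl groups available for methylotrophic methanogenesis, per molecule.
# Extensible: add osmolytes here without touching code.
TMA: 3
TMAO: 3
choline: 3
glycine_betaine: 3
DMSP: 2
DMS: 2
methylamine: 1
dimethylamine: 2
methanol: 1
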