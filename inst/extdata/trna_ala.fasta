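>Ala partially reconstructed; worked-example segments 1-10, 34-45, 54-72 as printed
GAGGAUUUAGUUAGUGUAGUGUAGUGAUUGACUUGCAUUCAAUUGAUAGAUUGUUCUAAGCAAUCCUUACCA
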