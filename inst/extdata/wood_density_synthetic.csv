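species,density_kg_m3
Platanus x acerifolia,537
Fraxinus excelsior,560
Tilia x europaea,420
Quercus robur,590
Acer pseudoplatanus,510
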