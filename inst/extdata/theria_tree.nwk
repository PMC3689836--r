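(Didelphis,(Zhelestid,(Ukhaatherium,((Kulbeckia,Zalambdalestes)E,((((Chrysochloris,Hemicentetes)I,Macroscelides)H,(Elephantimorpha,(Procavia,Trichechus)K)J,Orycteropus)G,Dasypus,(((((Bathygenys,(Sus,(Tursiops,Balaenopteridae)R)Q)P,Equus)O,(Manis,(Felis,(Canis,Eumetopias)U)T)S,(Pteropus,(Nycteris,(Rhinolophus,Tadarida)X)W)V)N,(Atelerix,Sorex)Y)M,(((Cavia,Mus)b,(Lepus,Sylvilagus)c)a,(Cynocephalus,(Homo,Macaca)e)d,Tupaia)Z)L)F)D)C)B)A;
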