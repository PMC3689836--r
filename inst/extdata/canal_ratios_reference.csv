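"taxon_id","norm_ant","norm_lat","norm_post","norm_avg","lr_ant","lr_lat","lr_post"
"Didelphis",0.05,0.03,0.04,0.04,5.63,5.47,6.11
"Kulbeckia",,,,,4.8,4.29,4.75
"Ukhaatherium",,,,,4.55,4.28,4.88
"Zalambdalestes",,,,,4.77,4.36,4.53
"Zhelestid",,,,,4.96,4.4,5.15
"Chrysochloris",2.47,1.52,1.598,1.8613,4.3,3.89,5.07
"Elephantimorpha",,,,,4.93,4.7,4.41
"Hemicentetes",1,0.62,0.8045,0.8068,4.52,3.59,5.41
"Macroscelides",3.43,2.74,2.667,2.949,4.25,4,5.1
"Orycteropus",0.01,0.01,0.006,0.01,4.96,5.03,5.39
"Procavia",0.05,0.05,0.06,0.05,5.14,4.28,4.9
"Trichechus",0.001,0.001,0.001,0.001,4.02,3.18,4.67
"Dasypus",0.035,0.03,0.04,0.03,5.91,4.63,5.88
"Atelerix",0.14,0.1,0.14,0.13,4.74,4.15,4.74
"Balaenopteridae",,,,,4.19,4.05,4.94
"Bathygenys",,,,,5.08,4.68,5.59
"Canis",,,,,4.97,4.5,5.14
"Equus",0.001,0.001,0.001,0.001,4.79,4.02,5.32
"Eumetopias",4e-04,4e-04,4e-04,4e-04,4.33,4.72,4.92
"Felis",0.06,0.05,0.06,0.05,4.57,4.45,4.93
"Manis",0.03,0.02,0.04,0.03,4.52,3.49,4.23
"Nycteris",3.31,2.97,2.7,2.99,4.48,3.91,5.51
"Pteropus",0.36,0.3,0.31,0.32,4.37,4.56,5.2
"Rhinolophus",4.81,4.02,4.32,4.38,4.25,4.64,5.25
"Sorex",10.7,7.95,10.4,9.68,4.91,3.38,5.44
"Sus",0.003,0.002,0.003,0.003,4.86,3.87,4.89
"Tadarida",6.97,6.0395,6.0601,6.3556,4.62,4.45,4.88
"Tursiops",0.001,0.001,0.001,0.001,3.47,3.38,5.17
"Cavia",0.26,0.22,0.22,0.23,4.79,4.13,5.02
"Cynocephalus",0.19,0.15,0.17,0.17,5.15,4.75,4.94
"Homo",0.004,0.003,0.004,0.004,4.61,4.39,4.76
"Lepus",0.1,0.07,0.07,0.08,4.89,4.13,4.8
"Macaca",0.06,0.05,0.05,0.06,4.74,4.29,5.13
"Mus",5.01,3.89,4.31,4.4,4.98,4.12,5.39
"Sylvilagus",0.16,0.11,0.12,0.13,4.84,4.38,5.13
"Tupaia",1.32,1.1,1.14,1.18,5.35,5.46,5.4
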