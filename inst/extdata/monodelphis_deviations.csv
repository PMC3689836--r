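"specimen_id","ant_linear_dev_mm","lat_linear_dev_mm","post_linear_dev_mm","ant_lumen_mm","lat_lumen_mm","post_lumen_mm","ant_ratio","lat_ratio","post_ratio"
"TMM-M-7595",0,0,0,0.2,0.27,0.26,0,0,0
"TMM-M-8261",0.08,0,0.08,0.21,0.24,0.18,0.38,0,0.44
"TMM-M-8265",0.05,0,0.08,0.29,0.25,0.22,0.17,0,0.36
"TMM-M-7536",0.11,0.05,0.07,0.19,0.19,0.24,0.58,0.26,0.29
"TMM-M-8266",0.11,0.05,0.07,0.19,0.19,0.19,0.58,0.26,0.37
"TMM-M-7539",0,0,0.1,0.21,0.19,0.22,0,0,0.45
"TMM-M-7542",0.08,0,0.06,0.23,0.22,0.25,0.35,0,0.24
"TMM-M-8267",0.07,0.05,0.06,0.17,0.19,0.22,0.41,0.26,0.27
"TMM-M-7545",0.1,0.05,0.09,0.17,0.25,0.27,0.59,0.2,0.33
"TMM-M-8268",0.11,0.04,0.09,0.17,0.2,0.2,0.65,0.2,0.45
"TMM-M-8273",0.11,0.07,0.09,0.23,0.2,0.24,0.48,0.35,0.38
"TMM-M-7599",0.07,0.06,0.07,0.18,0.2,0.26,0.39,0.3,0.27
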