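name,PA 0,RAO 10/CAU 30,RAO 30/CAU 30,RAO 30,RAO 30/CRA 30,LAO 10/CRA 30,LAO 30/CRA 30,LAO 45/CRA 30,LAO 45,LAO 45/CAU 30
PA 0,NA,,,,,,,,,
RAO 10/CAU 30,3063,NA,,,,,,,,
RAO 30/CAU 30,1162,5381,NA,,,,,,,
RAO 30,4357,1891,3700,NA,,,,,,
RAO 30/CRA 30,1735,0,0,4778,NA,,,,,
LAO 10/CRA 30,3824,0,0,943,2115,NA,,,,
LAO 30/CRA 30,1940,0,0,0,0,7038,NA,,,
LAO 45/CRA 30,27,0,0,0,0,2232,7016,NA,,
LAO 45,197,0,0,0,0,917,1859,2430,NA,
LAO 45/CAU 30,0,0,0,0,0,0,0,0,1769,NA
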