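name,PA 0,RAO 10/CAU 30,RAO 30/CAU 30,RAO 30,RAO 30/CRA 30,LAO 10/CRA 30,LAO 30/CRA 30,LAO 45/CRA 30,LAO 45,LAO 45/CAU 30
PA 0,NA,,,,,,,,,
RAO 10/CAU 30,1455,NA,,,,,,,,
RAO 30/CAU 30,261,3755,NA,,,,,,,
RAO 30,1894,527,948,NA,,,,,,
RAO 30/CRA 30,333,0,0,1650,NA,,,,,
LAO 10/CRA 30,1913,0,0,0,0,NA,,,,
LAO 30/CRA 30,694,0,0,0,0,5182,NA,,,
LAO 45/CRA 30,0,0,0,0,0,0,4819,NA,,
LAO 45,0,0,0,0,0,0,49,55,NA,
LAO 45/CAU 30,0,0,0,0,0,0,0,0,56,NA
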