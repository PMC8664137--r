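name,table_height_cm,ld_mm,ccd_mm,total_panning_mm,sid_mm,ssd_mm,ap_mm2,as_mm2,ratio_as_ap
PA 0,15,0,0,0,976,593,10738,10991,1.02
RAO 10/CAU 30,15,-8,-28,29,1049,571,8639,10430,1.21
RAO 30/CAU 30,15,-28,-32,43,1083,570,8083,9759,1.21
RAO 30,15,-28,0,28,1024,590,9668,10800,1.12
RAO 30/CRA 30,15,-28,32,43,1066,581,8661,11016,1.27
LAO 10/CRA 30,15,8,28,29,1016,587,9720,11006,1.13
LAO 30/CRA 30,15,28,32,43,1052,567,8472,11177,1.32
LAO 45/CRA 30,15,48,39,62,1105,558,7448,9574,1.29
LAO 45,15,48,0,48,1028,568,8898,10425,1.17
LAO 45/CAU 30,15,48,-39,62,1068,547,7659,9768,1.28
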