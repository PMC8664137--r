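name,table_height_cm,ld_mm,ccd_mm,total_panning_mm,sid_mm,ssd_mm,ap_mm2,as_mm2,ratio_as_ap
PA 0,15,0,0,0,947,599,11629,11914,1.02
RAO 10/CAU 30,15,-5,-16,17,1027,571,9009,11405,1.27
RAO 30/CAU 30,15,-16,-18,24,1055,570,8513,11556,1.36
RAO 30,15,-16,0,16,982,596,10716,12843,1.20
RAO 30/CRA 30,15,-16,18,24,1020,589,9710,12838,1.32
LAO 10/CRA 30,15,5,16,17,973,595,10876,12030,1.11
LAO 30/CRA 30,15,16,18,24,1009,576,9492,12161,1.28
LAO 45/CRA 30,15,27,22,35,1054,570,8528,11350,1.33
LAO 45,15,27,0,27,988,579,9997,11985,1.20
LAO 45/CAU 30,15,27,-22,35,1043,551,8143,11055,1.36
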