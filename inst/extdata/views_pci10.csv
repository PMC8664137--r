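name,primary_deg,secondary_deg
PA 0,0,0
RAO 10/CAU 30,-10,-30
RAO 30/CAU 30,-30,-30
RAO 30,-30,0
RAO 30/CRA 30,-30,30
LAO 10/CRA 30,10,30
LAO 30/CRA 30,30,30
LAO 45/CRA 30,45,30
LAO 45,45,0
LAO 45/CAU 30,45,-30
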