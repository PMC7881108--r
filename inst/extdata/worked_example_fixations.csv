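"participant","condition","onset_ms","duration_ms","aoi"
"P01","MD",0,250,1
"P01","MD",290,180,1
"P01","MD",510,300,4
"P01","MD",850,150,4
"P01","MD",1040,60,5
"P01","MD",1140,220,1
"P01","MD",1400,150,2
"P01","MD",1590,90,2
"P01","MD",1720,400,1
"P01","MD",2160,130,1
"P01","MD",2330,200,2
"P01","MD",2570,120,2
"P01","MD",2730,90,6
"P01","MD",2860,110,6
"P01","MD",3010,310,2
"P01","MD",3360,100,0
"P01","MD",3500,75,0
"P01","MD",3615,95,0
"P01","MD",3750,260,1
"P01","MD",4050,140,1
"P01","MD",4230,190,3
"P01","MD",4460,70,4
"P01","MD",4570,210,1
"P01","MD",4820,85,1
"P01","MD",4945,330,3
"P01","MD",5315,150,3
"P01","MD",5505,95,3
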