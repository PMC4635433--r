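biome,forest,b_leaf,b_wood,b_froot,b_croot,LN,Lleaf,Lfroot,Lwood,c_1,c_2,c_3,c_4,c_5,c_6,c_7,c_8,c_9,c_10,c_11,c_12,c_13
ENF,TRUE,0.25,0.35,0.3,0.1,30,0.22,0.25,0.35,0.35,0.035,0.6,0.07,14.8,3.9,18.5,4.9,0.25,6,7.3,0.2,0.0045
EBF,TRUE,0.3,0.35,0.25,0.1,25,0.2,0.25,0.35,0.7,0.04,0.7,0.08,14.8,3.9,18.5,4.9,0.25,6,7.3,0.2,0.0045
DNF,TRUE,0.25,0.45,0.2,0.1,30,0.22,0.25,0.35,0.35,0.022,0.6,0.06,14.8,3.9,18.5,4.9,0.25,6,7.3,0.2,0.0045
DBF,TRUE,0.22,0.5,0.18,0.1,25,0.2,0.25,0.35,0.6,0.013,0.6,0.05,14.8,3.9,18.5,4.9,0.25,6,7.3,0.2,0.0045
MF,TRUE,0.25,0.4,0.25,0.1,27,0.21,0.25,0.35,0.5,0.025,0.6,0.06,14.8,3.9,18.5,4.9,0.25,6,7.3,0.2,0.0045
CSH,FALSE,0.42,0.04,0.44,0.1,22,0.18,0.22,0.3,0.9,0.09,0.8,0.25,14.8,3.9,18.5,4.9,0.25,6,7.3,0.25,0.006
OSH,FALSE,0.42,0.04,0.44,0.1,22,0.18,0.22,0.3,0.9,0.09,0.8,0.25,14.8,3.9,18.5,4.9,0.25,6,7.3,0.25,0.006
WL,FALSE,0.45,0.02,0.43,0.1,18,0.15,0.2,0.3,1,0.06,0.8,0.25,14.8,3.9,18.5,4.9,0.25,6,7.3,0.25,0.006
GRA,FALSE,0.45,0,0.45,0.1,15,0.12,0.18,0.3,1.2,0.06,0.70,0.22,14.8,3.9,18.5,4.9,0.25,6,7.3,0.25,0.006
CRO,FALSE,0.45,0,0.45,0.1,12,0.1,0.15,0.3,1.1,0.06,0.75,0.25,14.8,3.9,18.5,4.9,0.25,6,7.3,0.25,0.006
CRN,FALSE,0.48,0.02,0.4,0.1,14,0.12,0.17,0.3,1.2,0.06,0.85,0.28,14.8,3.9,18.5,4.9,0.25,6,7.3,0.25,0.006
BAR,FALSE,0.45,0,0.45,0.1,15,0.12,0.18,0.3,1,0.06,0.8,0.25,14.8,3.9,18.5,4.9,0.25,6,7.3,0.25,0.006
TUN,FALSE,0.42,0.03,0.45,0.1,20,0.18,0.22,0.3,0.8,0.08,0.7,0.25,14.8,3.9,18.5,4.9,0.25,6,7.3,0.25,0.006
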