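compound,KD_nmr_uM,LE_nmr,KD_spr_uM,LE_spr,NHA
1,186,0.24,269,0.23,21
2,106,0.22,126,0.22,NA
3,352,0.17,205,0.18,NA
4,62,0.21,114,0.20,NA
5,32,0.215,49,0.21,NA
6,50,0.20,58,0.20,NA
7,34,0.19,44,0.19,NA
8,85,0.20,75,0.20,NA
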