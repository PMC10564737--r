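compound,KD_spr_uM,KD_itc_uM,dG_kcal_mol,dH_kcal_mol,minusTdS_kcal_mol,LE
9,4.2,2.6,-7.65,-4.1,-3.55,0.21
10,3.7,1.1,-8.12,-5.81,-2.31,0.23
11,2.7,1.0,-8.23,-5.25,-2.98,0.22
12,2.2,0.51,-8.59,-8.16,-0.43,0.23
13,2.4,0.38,-8.75,-7.13,-1.62,0.23
14,2.4,0.48,-8.61,-6.31,-2.26,0.23
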