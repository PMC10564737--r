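parameter,value,unit,text_value
k_inact,2.1e-4,s^-1,
K_I,3.6e-6,M,
covalent_efficiency,58,M^-1 s^-1,
probe_K_L,77.56e-9,M,
Ki_t0,1.1e-6,M,
Ki_itc,2.2e-6,M,
gsh_half_life_lower_bound,70,min,
adduct_mass,542,Da,
dsf_shift,6,C,
cetsa_ec50_8h,2.5e-6,M,
pY_KD,190e-6,M,
pY_NHA,17,count,
pY_LE,0.29,kcal/mol/NHA,
compound1_KD_nmr,186e-6,M,
compound1_NHA,21,count,
compound1_LE,0.24,kcal/mol/NHA,
ligand_composition,,formula,C(26)H(26)ClFN(3)O(7)P
adduct_composition,,formula,C(26)H(25)N(3)O(7)FP
maxquant_modification,,formula,C(26)H(25)N(3)O(7)FPSe(-1)S
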