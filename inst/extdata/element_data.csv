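# radyield element reference table, v1 (2026-10)
# z: atomic number; molar_mass_gmol: natural-abundance molar mass;
# i_ev: mean excitation potential
symbol,z,molar_mass_gmol,i_ev
H,1,1.008,19.2
C,6,12.011,78
N,7,14.007,82
O,8,15.999,95
Al,13,26.982,166
Ti,22,47.867,233
Cu,29,63.546,322
Yb,70,173.045,684
Lu,71,174.967,694
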