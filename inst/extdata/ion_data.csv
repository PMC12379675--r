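# radyield projectile table, v1 (2026-10); rest masses in MeV (CODATA-2018)
symbol,name,z,rest_mass_mev
p,proton,1,938.27208816
d,deuteron,1,1875.61292857
t,triton,1,2808.92113298
a,alpha,2,3727.3794066
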