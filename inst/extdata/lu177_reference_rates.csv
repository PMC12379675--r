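# Published ion-formation rates for 10 mA, 18 MeV deuterons on a 0.36 mm
# 99 % enriched Yb2O3 target (18 -> 8 MeV), by dataset.  These are scenario
# inputs, usable in place of rates recomputed from the fixture library.
# default = 1 marks the dataset used for each reaction in the reference
# yield tables.
reaction,dataset,rate_atoms_per_s,default
dp_yb177,nagai,1.065e13,1
dp_yb177,tendl_dagger,1.070e13,0
dng_lu177m,tendl_dagger,2.122e11,1
dn_lu177g,nagai,3.853e11,1
dn_lu177g,tendl_dagger,6.051e11,0
d2ng_lu176m,nagai,9.02e12,1
d2ng_lu176m,tendl_dagger,1.179e13,0
d2n_lu176g,tendl_dagger,1.259e13,1
d3n_lu175,tendl_dagger,2.885e13,1
d4ng_lu174m,nagai,1.418e10,1
d4ng_lu174m,tendl_dagger,9.837e7,0
d4n_lu174g,nagai,4.642e11,1
d4n_lu174g,tendl_dagger,3.025e8,0
d_nonelastic,tendl_dagger,7.105e13,1
d_burnup,tendl_dagger,6.07e13,1
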