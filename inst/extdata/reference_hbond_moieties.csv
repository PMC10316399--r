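# Published reference values: average numbers of intermolecular hydrogen
# bonds per GSL molecule, by sugar moiety, for GSLs in DOPC/Chol/SM
# (65/25/10/5) bilayer nanodomains (atomistic MD). "total" rows are the
# printed per-species totals; SM-SM is the sphingomyelin reference.
species,moiety,bonds,se
GD1a,Sia6,2.5,0.0
GD1a,Gal5,1.6,0.0
GD1a,GalNAc4,1.1,0.0
GD1a,Sia3,2.2,0.1
GD1a,Gal2,2.1,0.0
GD1a,Glc1,0.5,0.0
GD1a,total,10.0,NA
GM1,Gal5,2.0,0.1
GM1,GalNAc4,1.1,0.0
GM1,Sia3,2.1,0.1
GM1,Gal2,0.4,0.0
GM1,Glc1,0.6,0.0
GM1,total,6.2,NA
GM3,Sia3,2.6,0.2
GM3,Gal2,1.4,0.1
GM3,Glc1,0.7,0.1
GM3,total,4.7,NA
asialoGM1,Gal5,1.0,0.0
asialoGM1,GalNAc4,0.9,0.0
asialoGM1,Gal2,0.4,0.0
asialoGM1,Glc1,0.5,0.0
asialoGM1,total,2.8,NA
SM,SM-SM,1.0,NA
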