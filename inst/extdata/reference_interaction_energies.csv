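# Published reference values: average interaction energies (kJ/mol)
# between GSL sugar headgroups (GSL/GSL, homogeneous) and between GSL
# headgroups and bulk lipids (heterogeneous), total per GSL molecule and
# normalized by the number of interacting partners.
species,partner_class,total_kJ_mol,normalized_kJ_mol
GD1a,GSL/GSL,-51,-4.3
GD1a,DOPC,-298,-3.3
GD1a,SM,-86,-3.3
GD1a,Chol,-78,-1.2
GM1,GSL/GSL,-56,-4.7
GM1,DOPC,-247,-2.7
GM1,SM,-123,-4.7
GM1,Chol,-83,-1.3
asialoGM1,GSL/GSL,-35,-2.9
asialoGM1,DOPC,-267,-3.0
asialoGM1,SM,-101,-3.9
asialoGM1,Chol,-88,-1.4
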