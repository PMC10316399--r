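# Published reference values: average numbers of hydrogen bonds between
# GSL headgroups (or single Sia moieties) and water, per GSL molecule,
# for GSLs inside nanodomains and for one isolated GSL molecule in a
# DOPC/Chol/SM (65/25/10) bilayer. fraction_pct is the printed percentage
# of headgroup-water bonds contributed by the Sia moiety.
species,group,mode,bonds,se,fraction_pct
GD1a,headgroup,nanodomain,43.5,0.4,NA
GD1a,Sia1,nanodomain,12.1,0.1,27.8
GD1a,Sia2,nanodomain,12.6,0.0,29.0
GM1,headgroup,nanodomain,32.6,0.1,NA
GM1,Sia1,nanodomain,12.2,0.0,37.4
asialoGM1,headgroup,nanodomain,22.0,0.4,NA
SM,headgroup,nanodomain,4.3,0.0,NA
GD1a,headgroup,isolated,44.6,0.4,NA
GD1a,Sia1,isolated,12.6,0.2,28.3
GD1a,Sia2,isolated,13.5,0.2,30.3
GM1,headgroup,isolated,34.3,0.2,NA
GM1,Sia1,isolated,13.1,0.1,38.1
asialoGM1,headgroup,isolated,22.9,0.7,NA
SM,headgroup,isolated,4.5,0.0,NA
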