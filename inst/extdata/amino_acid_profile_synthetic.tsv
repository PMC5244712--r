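monomer	mole_fraction
ala	0.095
arg	0.045
asn	0.040
asp	0.055
cys	0.010
gln	0.040
glu	0.065
gly	0.090
his	0.018
ile	0.055
leu	0.085
lys	0.050
met	0.020
phe	0.038
pro	0.045
ser	0.055
thr	0.055
trp	0.012
tyr	0.027
val	0.100
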