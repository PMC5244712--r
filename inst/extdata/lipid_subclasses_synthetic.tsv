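monomer	mole_fraction
SQDG	0.20
MGDG	0.40
DGDG	0.25
PGP	0.15
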