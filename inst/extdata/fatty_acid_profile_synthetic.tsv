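monomer	mole_fraction
fa14	0.10
fa16	0.55
fa18	0.35
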