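macromolecule	mass_fraction_N2	mass_fraction_KNO3	coefficient_N2	coefficient_KNO3	subset_of
protein	0.289	0.438	2.12e-4	2.66e-4
phycoerythrin	1.54e-2	3.67e-2	2.64e-2	4.46e-4	protein
cyanophycin	3.80e-2	9.33e-2	6.96e-2	4.31e-2	protein
carbohydrate	0.265	0.351	4.59e-1	5.33e-1
rna	9.18e-2	6.51e-2	2.88e-3	2.46e-3
dna	4.28e-2	2.40e-2	1.39e-3	1.09e-3
lipids	0.137	7.40e-2	3.89e-3	3.00e-3
phycocyanin	2.60e-2	3.67e-2	4.45e-2	5.37e-2	lipids
chlorophyll	8.91e-3	0.424e-3	9.99e-3	7.37e-3	lipids
soluble_pool	2.86e-2	2.86e-2	3.79e-2	3.79e-2
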