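# Synthetic curation of the 40-flavonoid benchmark set: well-known structures
# entered from standard nomenclature; entries whose exact published structure
# could not be pinned (database codes, rare prenylflavanones, biflavone methyl
# ethers, ascorbyl adducts) are representative reconstructions of the named
# compound class. 2D constitution only (no stereochemistry).
O=c1c(-c2ccc(O)cc2)coc2cc(O)ccc12	Daidzein
O=c1c(-c2ccc(O)cc2)coc2cc(O)cc(O)c12	Genistein
O=c1c(-c2ccc(O)c(O)c2)coc2cc(O)ccc12	3',4',7-Trihydroxyisoflavone
COc1ccc(-c2coc3cc(O)c(O)cc3c2=O)cc1	CHEMBL4870006
CC(C)=CCc1c(O)ccc2c1occ(-c1ccc(O)cc1)c2=O	Maduraktermol H
O=c1c(-c2ccccc2O)coc2cc(O)ccc12	CHEMBL4878391
COc1ccc2c(c1)occ(-c1ccc(OC)c(OC)c1)c2=O	7,3',4'-Trimethoxyisoflavone
COc1ccc(-c2coc3ccccc3c2=O)cc1	CHEMBL4874262
COc1c(O)cc(O)c2c(=O)cc(-c3ccccc3)oc12	Wogonin
COc1c(O)cc2oc(-c3ccccc3)cc(=O)c2c1O	Oroxylin A
O=C(OC1Cc2c(O)cc(O)cc2OC1c1ccc(O)cc1)c1cc(O)c(O)c(O)c1	(-)-Epiafzelechin 3-O-gallate
O=C(OC1Cc2c(O)cc(O)cc2OC1c1ccc(O)c(O)c1)c1cc(O)c(O)c(O)c1	(-)-Epicatechin 3-O-gallate
O=C(OC1Cc2c(O)cc(O)cc2OC1c1cc(O)c(O)c(O)c1)c1cc(O)c(O)c(O)c1	(-)-Epigallocatechin 3-O-gallate
O=C(C=Cc1ccc(O)cc1)OC1Cc2c(O)cc(O)cc2OC1c1cc(O)c(O)c(O)c1	(-)-Epigallocatechin 3-O-p-coumaroate
O=C(OC1Cc2c(O)cc(O)cc2OC1c1cc(O)c(O)c(O)c1)c1cc(O)c(O)c(O)c1	(-)-Gallocatechin 3-O-gallate
OCC(O)C1OC(=O)C(c2c(O)cc(O)c3c2OC(c2cc(O)c(O)c(O)c2)C(O)C3)=C1O	8-C-ascorbyl (-)-epigallocatechin
COc1ccc(-c2cc(=O)c3c(OC)c(OC)c(OC)c(OC)c3o2)cc1	Tangeretin
COc1ccc(-c2cc(=O)c3c(OC)c(OC)c(OC)c(OC)c3o2)cc1OC	Nobiletin
COc1ccc(-c2cc(=O)c3c(O)c(OC)c(OC)c(OC)c3o2)cc1OC	5-Demethylnobiletin
O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12	Quercetin
COc1ccc(-c2cc(=O)c3c(O)cc(O)c(-c4c(O)cc5oc(-c6ccc(O)cc6)cc(=O)c5c4O)c3o2)cc1	Bilobetin
COc1ccc(-c2cc(=O)c3c(O)cc(OC)c(-c4c(O)cc5oc(-c6ccc(O)cc6)cc(=O)c5c4O)c3o2)cc1	Ginkgetin
O=C1CC(c2cc(O)cc(O)c2)Oc2cc(O)cc(O)c21	5,7,3',5'-Tetrahydroxyflavanone
CC(C)=CCc1c(O)cc2c(c1O)C(=O)CC(c1ccc(O)cc1)O2	8-Prenylnaringenin
CC(C)=CCc1c(O)cc2c(c1O)C(=O)CC(c1ccc(O)cc1O)O2	Cudraflavanone A
CC(C)(O)CCc1c(O)cc2c(c1O)C(=O)CC(c1cc3C=CC(C)(C)Oc3cc1O)O2	2',5,7-Trihydroxy-4,5'-(2,2-dimethylchromeno)-8-(3-hydroxy-3-methylbuthyl)flavanone
O=c1cc(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12	Luteolin
CC1OC(OCC2OC(Oc3c(-c4ccc(O)cc4)oc4cc(O)cc(O)c4c3=O)C(O)C(O)C2O)C(O)C(O)C1O	Kaempferol-3-Orutinoside
CC1OC(OCC2OC(Oc3c(-c4ccc(O)c(O)c4)oc4cc(O)cc(O)c4c3=O)C(O)C(O)C2O)C(O)C(O)C1O	Rutin
COc1ccc(-c2coc3cc(O)ccc3c2=O)cc1	Formononetin
COc1ccc(-c2coc3c(O)c(O)ccc3c2=O)cc1	7,8-Dihydroxy-4'-methoxyisoflavone
COc1ccc(-c2coc3cc(O)cc(O)c3c2=O)cc1	CHEMBL4859886
COc1cc(C(=O)OC2Cc3c(O)cc(O)cc3OC2c2ccc(O)c(O)c2)cc(O)c1O	(-)-Epicatechin 3-O-(3'-O-methyl)gallate
O=C(OC1Cc2c(O)cc(O)cc2OC1c1ccc(O)c(O)c1)c1cc(O)c(O)c(O)c1	(-)-Catechin 3-O-gallate
OCC(O)C1OC(=O)C(c2c(O)cc(O)c3c2OC(c2cc(O)c(O)c(O)c2)C(OC(=O)c2cc(O)c(O)c(O)c2)C3)=C1O	8-C-ascorbyl (-)-epigallocatechin 3-O-gallate
COc1ccc(-c2cc(=O)c3c(O)c(OC)c(OC)c(OC)c3o2)cc1	5-Demethyltangeretin
COc1ccc(-c2cc(=O)c3c(O)cc(O)c(-c4c(O)cc5oc(-c6ccc(OC)cc6)cc(=O)c5c4O)c3o2)cc1	Isoginkgetin
COc1ccc(-c2cc(=O)c3c(O)cc(OC)c(-c4c(O)cc5oc(-c6ccc(OC)cc6)cc(=O)c5c4O)c3o2)cc1	Sciadopitysin
CC(C)=CCc1c(O)cc2c(c1O)C(=O)C(CC=C(C)C)C(c1ccc(O)cc1O)O2	Cudraflavanone D
CC(C)=CCc1c(O)cc2c(c1O)C(=O)CC(c1ccc(O)c(CC=C(C)C)c1O)O2	Cudracuspiflavanone A
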