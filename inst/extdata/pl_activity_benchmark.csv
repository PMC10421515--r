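"name","pic50_exp","pic50_pred","residual","partition"
"Daidzein",4.081,4.037,0.044,"train"
"Genistein",4.222,4.05,0.172,"train"
"3',4',7-Trihydroxyisoflavone",4.155,3.957,0.198,"train"
"CHEMBL4870006",4.036,4.051,0.015,"train"
"Maduraktermol H",4.201,3.977,0.224,"train"
"CHEMBL4878391",4.06,4.072,0.011,"train"
"7,3',4'-Trimethoxyisoflavone",3.444,3.838,0.394,"train"
"CHEMBL4874262",3.914,3.707,0.207,"train"
"Wogonin",3.813,3.765,0.049,"train"
"Oroxylin A",4.251,4.007,0.244,"train"
"(-)-Epiafzelechin 3-O-gallate",5.588,5.912,0.323,"train"
"(-)-Epicatechin 3-O-gallate",6.345,6.07,0.275,"train"
"(-)-Epigallocatechin 3-O-gallate",6.457,6.181,0.276,"train"
"(-)-Epigallocatechin 3-O-p-coumaroate",6.053,6.256,0.203,"train"
"(-)-Gallocatechin 3-O-gallate",6.36,6.181,0.178,"train"
"8-C-ascorbyl (-)-epigallocatechin",6.19,6.268,0.079,"train"
"Tangeretin",4.833,4.763,0.07,"train"
"Nobiletin",4.88,4.876,0.004,"train"
"5-Demethylnobiletin",5.379,5.294,0.085,"train"
"Quercetin",3.836,4.134,0.298,"train"
"Bilobetin",5.447,5.133,0.315,"train"
"Ginkgetin",5.161,5.706,0.545,"train"
"5,7,3',5'-Tetrahydroxyflavanone",4.087,4.182,0.094,"train"
"8-Prenylnaringenin",4.114,4.19,0.076,"train"
"Cudraflavanone A",5.187,5.229,0.041,"train"
"2',5,7-Trihydroxy-4,5'-(2,2-dimethylchromeno)-8-(3-hydroxy-3-methylbuthyl)flavanone",4.073,4.33,0.257,"train"
"Luteolin",3.573,3.755,0.182,"train"
"Kaempferol-3-Orutinoside",5.538,5.335,0.203,"train"
"Rutin",3.827,3.85,0.023,"train"
"Formononetin",3.921,3.765,0.156,"test"
"7,8-Dihydroxy-4'-methoxyisoflavone",4.032,4.128,0.097,"test"
"CHEMBL4859886",4,3.998,0.002,"test"
"(-)-Epicatechin 3-O-(3'-O-methyl)gallate",6.167,5.755,0.413,"test"
"(-)-Catechin 3-O-gallate",6.265,6.039,0.226,"test"
"8-C-ascorbyl (-)-epigallocatechin 3-O-gallate",6.102,6.696,0.594,"test"
"5-Demethyltangeretin",5.444,5.793,0.349,"test"
"Isoginkgetin",5.538,5.421,0.117,"test"
"Sciadopitysin",4.893,4.674,0.219,"test"
"Cudraflavanone D",5.046,5.493,0.448,"test"
"Cudracuspiflavanone A",4.261,4.115,0.146,"test"
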