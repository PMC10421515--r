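"id","ic50_pre_uM","water_solubility","bioavailability_score","gi_absorption","pgp_substrate","log_kp","carcino_mouse","carcino_rat"
"CNP0186639",0.49,"Moderately soluble",0.17,"Low","No",-7.55,"negative","positive"
"CNP0221970",0.61,"Moderately soluble",0.17,"Low","No",-7.94,"negative","positive"
"CNP0358253",0.73,"Moderately soluble",0.17,"Low","No",-7.55,"negative","positive"
"CNP0286940",0.85,"Moderately soluble",0.17,"Low","No",-9.24,"negative","negative"
"CNP0206087",1.27,"Moderately soluble",0.17,"Low","No",-8.87,"negative","positive"
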