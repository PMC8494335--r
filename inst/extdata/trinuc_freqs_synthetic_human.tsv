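context	frequency
ACA	0.040640406404064
ACC	0.025820258202582
ACG	0.00625506255062551
ACT	0.0407054070540705
ATA	0.0531505315053151
ATC	0.0330553305533055
ATG	0.040350403504035
ATT	0.0530705307053071
CCA	0.031030310303103
CCC	0.0192351923519235
CCG	0.004830048300483
CCT	0.0314553145531455
CTA	0.0402554025540255
CTC	0.026640266402664
CTG	0.031140311403114
CTT	0.04070040700407
GCA	0.0260352603526035
GCC	0.0159551595515955
GCG	0.0038650386503865
GCT	0.0253052530525305
GTA	0.032290322903229
GTC	0.02070020700207
GTG	0.02590025900259
GTT	0.034530345303453
TCA	0.040790407904079
TCC	0.025540255402554
TCG	0.00619006190061901
TCT	0.041270412704127
TTA	0.0538055380553806
TTC	0.0333953339533395
TTG	0.0411054110541105
TTT	0.0549855498554986
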