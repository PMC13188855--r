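class,count
PHA,2657
PHB,1804
PBAT,253
PBS,75
PBSA,469
PLA,1195
PCL,1367
PET,1473
PU,313
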