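class,count
PHA,50
PHB,46
PBAT,16
PBS,11
PBSA,16
PLA,26
PCL,40
PET,75
PU,14
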