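ADCY10
HFE
MUC1
PPIEL
AK5
PRKACB
ITGB1BP2
KMO
TYRP1
NEAT1
PKI55
SMPDL3A
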