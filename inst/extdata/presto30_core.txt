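ADCY10
HFE
MUC1
PPIEL
SNORD81
AK5
HOXC-AS1
NAALADL2
PRKACB
STEAP3-AS1
CATSPER3
ITGB1BP2
NAALADL2-AS2
RASD2
SYAP1
CHMP1B2P
KMO
NCKAP5
SLC26A4-AS1
TYRP1
DNAH11
LOC100289561
NEAT1
SLC30A8
ZNF32-AS2
GATA2-AS1
LOC101927708
PKI55
SMPDL3A
ZNF626
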