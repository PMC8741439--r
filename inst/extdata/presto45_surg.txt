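ANLN
CENPF
ESCO2
KIF23
PRSS8
TOP2A
ASF1B
CKAP2L
FAM83D
KIF2C
RAB6C
TPX2
ASPG
DEGS2
FBXO43
LOC100506474
RAB6C-AS1
TROAP
ASPM
DLGAP5
HMMR
LOC728752
RIBC2
TTK
BIRC5
DSCR9
IQGAP3
MELK
RRM2
UBE2C
CDC25C
DTL
KIF14
MKI67
SPATA24
CDCA2
E2F7
KIF15
NCAPG
STIL
CENPA
ERBB3
KIF18B
PBK
TMEM25
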