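ANLN
CENPF
ESCO2
KIF23
TOP2A
ASF1B
CKAP2L
FAM83D
KIF2C
TPX2
TROAP
ASPM
DLGAP5
HMMR
TTK
BIRC5
IQGAP3
MELK
UBE2C
CDC25C
DTL
KIF14
MKI67
CDCA2
KIF15
NCAPG
STIL
CENPA
KIF18B
PBK
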