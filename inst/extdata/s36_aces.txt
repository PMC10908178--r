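# 36-gene signature selected on the ACES cohort
MAPT
BLVRA
CENPF
GRB7
BCL2
FGFR4
CDC6
CCNB1
FOXC1
KRT17
SFRP1
PTTG1
FOXA1
NDC80
KIF2C
MELK
MMP11
CEP55
SLC39A6
KRT14
MIA
NAT1
EGFR
EXO1
BIRC5
ACTR3B
CDH3
ESR1
MLPH
MDM2
CDC20
MYBL2
PGR
MYC
PHGDH
RRM2
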