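gene_id
HNF1B
KLK2
MYC
NFE2L2
POU5F1B
PTEN
RNASEL
SLC45A3
SOX2
SRD5A2
BRCA1
BRCA2
HOXB13
TP53
RAD51D
PALB2
NCOA3
MSR1
MSH2
MLH1
AIG1
ATM
BRAF
CDK12
CDKN1B
CHEK2
ELAC2
HIF1A
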