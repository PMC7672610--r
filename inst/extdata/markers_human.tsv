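gene	phase
CCNE1	G1.S
CCNE2	G1.S
CDC6	G1.S
CDC25A	G1.S
E2F1	G1.S
MCM2	G1.S
MCM6	G1.S
PCNA	G1.S
SLBP	G1.S
NASP	G1.S
GINS2	G1.S
CDT1	G1.S
CHAF1B	G1.S
DTL	G1.S
UHRF1	G1.S
RRM2	S
RRM1	S
CDC45	S
MCM4	S
POLA1	S
BRCA1	S
EXO1	S
TYMS	S
FEN1	S
RFC4	S
DSCC1	S
RAD51	S
CLSPN	S
USP1	S
HELLS	S
CCNA2	G2
CDK1	G2
TOP2A	G2
CCNF	G2
KIF11	G2
NDC80	G2
NUSAP1	G2
TACC3	G2
SMC4	G2
CKS1B	G2
MAD2L1	G2
EZH2	G2
HMGB2	G2
CKAP2	G2
BIRC5	G2
CCNB1	G2.M
CCNB2	G2.M
PLK1	G2.M
AURKA	G2.M
AURKB	G2.M
BUB1	G2.M
CDC20	G2.M
CENPA	G2.M
CENPE	G2.M
KIF20A	G2.M
TPX2	G2.M
UBE2C	G2.M
DLGAP5	G2.M
ANLN	G2.M
CDC25C	G2.M
RAD21	M.G1
CDKN3	M.G1
ANP32E	M.G1
TMPO	M.G1
PTTG1	M.G1
CTCF	M.G1
GTSE1	M.G1
KIF2C	M.G1
PSRC1	M.G1
CDCA3	M.G1
LBR	M.G1
NUF2	M.G1
MKI67	M.G1
AMD1	M.G1
TROAP	M.G1
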