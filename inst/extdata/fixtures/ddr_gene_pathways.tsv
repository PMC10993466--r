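gene	pathways
ATM	DDR_response
ATR	DDR_response
BARD1	HR
BLM	HR
BRCA1	FA,HR
BRCA2	FA,HR
BRIP1	FA,HR
CHEK2	DDR_response
DCLRE1C	NHEJ
DDB2	NER
DNA2	DR
ERCC1	NER
ERCC2	NER
ERCC3	NER
ERCC4	FA,NER
ERCC5	NER
ERCC6	NER
ERCC8	NER
FAN1	FA
FANCA	FA
FANCC	FA
FANCD2	FA
FANCE	FA
FANCF	FA
FANCG	FA
FANCI	FA
FANCL	FA
FANCM	FA
GTF2H5	NER
LIG1	NER,DR
LIG3	BER
LIG4	NHEJ
MCM2	DR
MCM4	DR
MCM5	DR
MCM7	DR
MLH1	MMR
MRE11	HR
MSH2	MMR
MSH3	MMR
MSH6	MMR
MUTYH	BER
NBN	HR
NHEJ1	NHEJ
NTHL1	BER
PALB2	FA,HR
PMS2	MMR
POLD1	DR
POLH	DR
POLK	DR
RAD50	HR
RAD51	FA,HR
RAD51B	HR
RAD51C	FA,HR
RAD51D	HR
RAD54L	HR
RBBP8	HR
RNASEH1	DR
RNASEH2A	DR
RNASEH2B	DR
RNASEH2C	DR
SLX4	FA
SSBP1	DR
TELO2	DDR_response
TOP3A	HR,DR
TP53	DDR_response
UBE2T	FA
UIMC1	HR
UNG	BER
XPA	NER
XPC	NER
XRCC1	BER
XRCC2	FA,HR
XRCC4	NHEJ
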