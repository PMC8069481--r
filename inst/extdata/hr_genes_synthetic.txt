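BRCA1
BRCA2
PALB2
RAD51
RAD51B
RAD51C
RAD51D
RAD52
RAD54L
RAD54B
XRCC2
XRCC3
BARD1
BRIP1
NBN
MRE11
RAD50
ATM
ATR
ATRX
CHEK1
CHEK2
FANCA
FANCB
FANCC
FANCD2
FANCE
FANCF
FANCG
FANCI
FANCL
FANCM
PTEN
WRN
BLM
RECQL
RECQL4
RECQL5
EXO1
DNA2
MUS81
EME1
EME2
GEN1
SLX1A
SLX4
ERCC1
ERCC4
RPA1
RPA2
RPA3
RPA4
TOP3A
TOP3B
TOPBP1
RMI1
RMI2
HELQ
POLD1
POLE
POLQ
PARP1
PARP2
PARP3
MDC1
H2AFX
TP53BP1
RIF1
SHLD1
SHLD2
SHLD3
MAD2L2
NHEJ1
PRKDC
XRCC5
XRCC6
LIG4
DCLRE1C
UIMC1
ABRAXAS1
BABAM1
BABAM2
BRCC3
USP1
UBE2T
WDR48
RNF8
RNF168
HERC2
PIAS1
PIAS4
SUMO1
UBE2I
CDK12
SWI5
SWSAP1
ZSWIM7
SPIDR
PARPBP
MCM8
MCM9
FIGNL1
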