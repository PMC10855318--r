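system,system_class,mechanism_category,n_strains_panel
RM,validated,nuclease_degradation,67
CRISPR-Cas,validated,nuclease_degradation,42
Gabija,validated,nuclease_degradation,39
Wadjet,validated,nuclease_degradation,24
Druantia,validated,nuclease_degradation,22
Shedu,validated,nuclease_degradation,17
Mokosh,validated,nuclease_degradation,16
Zorya,validated,nuclease_degradation,15
Septu,validated,nuclease_degradation,14
Mza,validated,nuclease_degradation,9
qatABCD,validated,nuclease_degradation,7
Ppl,validated,nuclease_degradation,4
Olokun,validated,nuclease_degradation,4
DISARM,validated,nuclease_degradation,3
Upx,validated,nuclease_degradation,3
Menshen,validated,nuclease_degradation,2
Azaca,validated,nuclease_degradation,2
Kiwa,validated,nuclease_degradation,1
Old,validated,nuclease_degradation,1
PD-T4-6,validated,abortive_infection,97
PD-T4-7,validated,abortive_infection,NA
PD-T7,validated,abortive_infection,NA
PD-Lambda,validated,abortive_infection,10
AbiE,validated,abortive_infection,NA
AbiD,validated,abortive_infection,NA
AbiU,validated,abortive_infection,NA
AbiL,validated,abortive_infection,NA
GAO_19,validated,abortive_infection,18
CBASS,validated,abortive_infection,42
Lamassu,validated,abortive_infection,26
ietAS,validated,abortive_infection,19
RosmerTA,validated,abortive_infection,13
PsyrTA,validated,abortive_infection,11
Hachiman,validated,abortive_infection,9
Helicase-DUF2290,validated,abortive_infection,8
Pycsar,validated,abortive_infection,8
AVAST,validated,abortive_infection,7
PrrC,validated,abortive_infection,5
PifA,validated,abortive_infection,4
Paris,validated,abortive_infection,2
ShosTA,validated,abortive_infection,2
darTG,validated,abortive_infection,1
BstA,validated,abortive_infection,1
DRT,validated,nucleic_acid_modification,24
Argonaute,validated,nucleic_acid_modification,16
BREX,validated,nucleic_acid_modification,14
Retron,validated,nucleic_acid_modification,11
PT_Ssp,validated,nucleic_acid_modification,NA
PT_Dnd,validated,nucleic_acid_modification,NA
RADAR,validated,nucleic_acid_modification,2
Dpd,validated,nucleic_acid_modification,1
MADS,validated,nucleic_acid_modification,1
SoFic,validated,protein_modification,88
Borvo,validated,protein_modification,2
TerY-P,validated,protein_modification,1
Dynamins,validated,other,6
Thoeris,validated,other,3
Dsr,validated,other,3
SEFIR,validated,other,1
DMS-other,DMS-other,unknown,69
HEC,HEC,unknown,41
Shango,validated,unknown,7
Tiamat,validated,unknown,5
Hma,validated,unknown,3
3HP,validated,unknown,3
DUF4238,validated,unknown,3
Juk,validated,unknown,1
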