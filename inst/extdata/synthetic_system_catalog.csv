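system,system_class,carriage_prob,effect_size
RM,validated,0.67,0.19
CRISPR-Cas,validated,0.42,0.19
Gabija,validated,0.39,0.19
Wadjet,validated,0.24,0.19
Druantia,validated,0.22,0.19
Shedu,validated,0.17,0.19
Mokosh,validated,0.16,0.19
Zorya,validated,0.15,0.19
Septu,validated,0.14,0.19
Mza,validated,0.09,0.19
qatABCD,validated,0.07,0.19
Ppl,validated,0.04,0.19
Olokun,validated,0.04,0.19
DISARM,validated,0.03,0.19
Upx,validated,0.03,0.19
Menshen,validated,0.02,0.19
Azaca,validated,0.02,0.19
Kiwa,validated,0.01,0.19
Old,validated,0.01,0.19
PD-T4-6,validated,0.97,0.19
PD-T4-7,validated,0.12,0.19
PD-T7,validated,0.08,0.19
PD-Lambda,validated,0.1,0.19
AbiE,validated,0.15,0.19
AbiD,validated,0.08,0.19
AbiU,validated,0.05,0.19
AbiL,validated,0.02,0.19
GAO_19,validated,0.18,0.19
CBASS,validated,0.42,0.19
Lamassu,validated,0.26,0.19
ietAS,validated,0.19,0.19
RosmerTA,validated,0.13,0.19
PsyrTA,validated,0.11,0.19
Hachiman,validated,0.09,0.19
Helicase-DUF2290,validated,0.08,0.19
Pycsar,validated,0.08,0.19
AVAST,validated,0.07,0.19
PrrC,validated,0.05,0.19
PifA,validated,0.04,0.19
Paris,validated,0.02,0.19
ShosTA,validated,0.02,0.19
darTG,validated,0.01,0.19
BstA,validated,0.01,0.19
DRT,validated,0.24,0.19
Argonaute,validated,0.16,0.19
BREX,validated,0.14,0.19
Retron,validated,0.11,0.19
PT_Ssp,validated,0.03,0.19
PT_Dnd,validated,0.02,0.19
RADAR,validated,0.02,0.19
Dpd,validated,0.01,0.19
MADS,validated,0.01,0.19
SoFic,validated,0.88,0.19
Borvo,validated,0.02,0.19
TerY-P,validated,0.01,0.19
Dynamins,validated,0.06,0.19
Thoeris,validated,0.03,0.19
Dsr,validated,0.03,0.19
SEFIR,validated,0.01,0.19
DMS-other,DMS-other,0.69,0.19
HEC,HEC,0.41,0.19
Shango,validated,0.07,0.19
Tiamat,validated,0.05,0.19
Hma,validated,0.03,0.19
3HP,validated,0.03,0.19
DUF4238,validated,0.03,0.19
Juk,validated,0.01,0.19
PDC-S02,PDC,0.39,0.19
PDC-S06,PDC,0.38,0.19
PDC-M30,PDC,0.32,0.19
PDC-S14,PDC,0.14,0.19
PDC-S08,PDC,0.12,0.19
PDC-S09,PDC,0.11,0.19
PDC-S11,PDC,0.1,0.19
PDC-S01,PDC,0.331,0.19
PDC-S03,PDC,0.302,0.19
PDC-S04,PDC,0.272,0.19
PDC-S05,PDC,0.245,0.19
PDC-S07,PDC,0.22,0.19
PDC-S10,PDC,0.198,0.19
PDC-S12,PDC,0.178,0.19
PDC-S13,PDC,0.161,0.19
PDC-S15,PDC,0.145,0.19
PDC-S16,PDC,0.13,0.19
PDC-S17,PDC,0.117,0.19
PDC-S18,PDC,0.105,0.19
PDC-S19,PDC,0.095,0.19
PDC-S20,PDC,0.085,0.19
PDC-S21,PDC,0.077,0.19
PDC-S22,PDC,0.069,0.19
PDC-S23,PDC,0.062,0.19
PDC-S24,PDC,0.056,0.19
PDC-S25,PDC,0.05,0.19
PDC-S26,PDC,0.045,0.19
PDC-S27,PDC,0.041,0.19
PDC-S28,PDC,0.037,0.19
PDC-S29,PDC,0.033,0.19
PDC-S30,PDC,0.03,0.19
PDC-S31,PDC,0.027,0.19
PDC-S32,PDC,0.024,0.19
PDC-S33,PDC,0.022,0.19
PDC-S34,PDC,0.02,0.19
PDC-S35,PDC,0.018,0.19
PDC-S36,PDC,0.016,0.19
PDC-S37,PDC,0.014,0.19
PDC-S38,PDC,0.013,0.19
PDC-S39,PDC,0.012,0.19
PDC-S40,PDC,0.01,0.19
PDC-S41,PDC,0.01,0.19
PDC-S42,PDC,0.01,0.19
PDC-S43,PDC,0.01,0.19
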