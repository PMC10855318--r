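stem,canonical
rm,RM
restriction_modification,RM
crispr_cas,CRISPR-Cas
crispr,CRISPR-Cas
cas,CRISPR-Cas
gabija,Gabija
wadjet,Wadjet
druantia,Druantia
shedu,Shedu
mokosh,Mokosh
zorya,Zorya
septu,Septu
mza,Mza
qatabcd,qatABCD
ppl,Ppl
olokun,Olokun
disarm,DISARM
upx,Upx
menshen,Menshen
azaca,Azaca
kiwa,Kiwa
old,Old
old_exonuclease,Old
pd_t4_6,PD-T4-6
pd_t4_7,PD-T4-7
pd_t7,PD-T7
pd_lambda,PD-Lambda
abie,AbiE
abid,AbiD
abiu,AbiU
abil,AbiL
gao_19,GAO_19
gao_29,GAO_29
cbass,CBASS
lamassu,Lamassu
lamassu_fam,Lamassu
ietas,ietAS
rosmerta,RosmerTA
psyrta,PsyrTA
rloc,PsyrTA
hachiman,Hachiman
helicase_duf2290,Helicase-DUF2290
duf2290,Helicase-DUF2290
pycsar,Pycsar
avast,AVAST
avs,AVAST
prrc,PrrC
pifa,PifA
paris,Paris
shosta,ShosTA
dartg,darTG
bsta,BstA
drt,DRT
retron,Retron
retrons,Retron
argonaute,Argonaute
pago,Argonaute
brex,BREX
pt_ssp,PT_Ssp
pt_dnd,PT_Dnd
radar,RADAR
dpd,Dpd
mads,MADS
sofic,SoFic
borvo,Borvo
tery_p,TerY-P
dynamins,Dynamins
dynamin,Dynamins
thoeris,Thoeris
dsr,Dsr
sefir,SEFIR
shango,Shango
tiamat,Tiamat
hma,Hma
3hp,3HP
duf4238,DUF4238
juk,Juk
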