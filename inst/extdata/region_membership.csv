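symbol,region
trnA-UGC,IR
trnC-GCA,LSC
trnD-GUC,LSC
trnE-UUC,LSC
trnF-GAA,LSC
trnfM-CAU,LSC
trnG-GCC,LSC
trnG-UCC,LSC
trnH-GUG,LSC
trnI-CAU,LSC
trnI-GAU,IR
trnK-UUU,LSC
trnL-CAA,LSC
trnL-UAA,LSC
trnL-UAG,SSC
trnM-CAU,LSC
trnN-GUU,IR
trnP-GGG,SSC
trnP-UGG,LSC
trnQ-UUG,LSC
trnR-ACG,IR
trnR-CCG,LSC
trnR-UCU,LSC
trnS-CGA,LSC
trnS-GCU,LSC
trnS-GGA,LSC
trnS-UGA,LSC
trnT-GGU,LSC
trnT-UGU,LSC
trnV-GAC,IR
trnV-UAC,LSC
trnW-CCA,LSC
trnY-GUA,LSC
rrn4.5,IR
rrn5,IR
rrn16,IR
rrn23,IR
psaA,LSC
psaB,LSC
psaC,LSC
psaI,LSC
psaJ,LSC
psaM,LSC
psbA,LSC
psbB,LSC
psbC,LSC
psbD,LSC
psbE,LSC
psbF,LSC
psbH,LSC
psbI,LSC
psbJ,LSC
psbK,LSC
psbL,LSC
psbM,LSC
psbN,LSC
psbT,LSC
psbZ,LSC
petA,LSC
petB,LSC
petD,LSC
petG,LSC
petL,LSC
petN,LSC
rbcL,LSC
atpA,LSC
atpB,LSC
atpE,LSC
atpF,LSC
atpH,LSC
atpI,LSC
chlB,LSC
chlL,SSC
chlN,SSC
ndhA,SSC
ndhB,LSC
ndhC,LSC
ndhD,SSC
ndhE,SSC
ndhF,SSC
ndhG,SSC
ndhH,SSC
ndhI,SSC
ndhJ,LSC
ndhK,LSC
rpl2,LSC
rpl14,LSC
rpl16,LSC
rpl20,LSC
rpl21,SSC
rpl22,LSC
rpl23,LSC
rpl32,SSC
rpl33,LSC
rpl36,LSC
rps2,LSC
rps3,LSC
rps4,LSC
rps7,LSC
rps8,LSC
rps11,LSC
rps12,LSC
rps14,LSC
rps15,SSC
rps16,LSC
rps18,LSC
rps19,LSC
rpoA,LSC
rpoB,LSC
rpoC1,LSC
rpoC2,LSC
infA,LSC
ccsA,SSC
matK,LSC
clpP,LSC
accD,LSC
cemA,LSC
ycf1,LSC
ycf2,LSC
ycf3,LSC
ycf4,LSC
ycf12,LSC
ycf66,LSC
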