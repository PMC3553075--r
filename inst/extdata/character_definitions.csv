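symbol,kind,class,host,position,direction,trans
trnA-UGC,gene,tRNA,NA,NA,loss,FALSE
trnC-GCA,gene,tRNA,NA,NA,loss,FALSE
trnD-GUC,gene,tRNA,NA,NA,loss,FALSE
trnE-UUC,gene,tRNA,NA,NA,loss,FALSE
trnF-GAA,gene,tRNA,NA,NA,loss,FALSE
trnfM-CAU,gene,tRNA,NA,NA,loss,FALSE
trnG-GCC,gene,tRNA,NA,NA,loss,FALSE
trnG-UCC,gene,tRNA,NA,NA,loss,FALSE
trnH-GUG,gene,tRNA,NA,NA,loss,FALSE
trnI-CAU,gene,tRNA,NA,NA,loss,FALSE
trnI-GAU,gene,tRNA,NA,NA,loss,FALSE
trnK-UUU,gene,tRNA,NA,NA,loss,FALSE
trnL-CAA,gene,tRNA,NA,NA,loss,FALSE
trnL-UAA,gene,tRNA,NA,NA,loss,FALSE
trnL-UAG,gene,tRNA,NA,NA,loss,FALSE
trnM-CAU,gene,tRNA,NA,NA,loss,FALSE
trnN-GUU,gene,tRNA,NA,NA,loss,FALSE
trnP-GGG,gene,tRNA,NA,NA,loss,FALSE
trnP-UGG,gene,tRNA,NA,NA,loss,FALSE
trnQ-UUG,gene,tRNA,NA,NA,loss,FALSE
trnR-ACG,gene,tRNA,NA,NA,loss,FALSE
trnR-CCG,gene,tRNA,NA,NA,loss,FALSE
trnR-UCU,gene,tRNA,NA,NA,loss,FALSE
trnS-CGA,gene,tRNA,NA,NA,loss,FALSE
trnS-GCU,gene,tRNA,NA,NA,loss,FALSE
trnS-GGA,gene,tRNA,NA,NA,loss,FALSE
trnS-UGA,gene,tRNA,NA,NA,loss,FALSE
trnT-GGU,gene,tRNA,NA,NA,loss,FALSE
trnT-UGU,gene,tRNA,NA,NA,loss,FALSE
trnV-GAC,gene,tRNA,NA,NA,loss,FALSE
trnV-UAC,gene,tRNA,NA,NA,loss,FALSE
trnW-CCA,gene,tRNA,NA,NA,loss,FALSE
trnY-GUA,gene,tRNA,NA,NA,loss,FALSE
rrn4.5,gene,rRNA,NA,NA,loss,FALSE
rrn5,gene,rRNA,NA,NA,loss,FALSE
rrn16,gene,rRNA,NA,NA,loss,FALSE
rrn23,gene,rRNA,NA,NA,loss,FALSE
psaA,gene,protein,NA,NA,loss,FALSE
psaB,gene,protein,NA,NA,loss,FALSE
psaC,gene,protein,NA,NA,loss,FALSE
psaI,gene,protein,NA,NA,loss,FALSE
psaJ,gene,protein,NA,NA,loss,FALSE
psaM,gene,protein,NA,NA,loss,FALSE
psbA,gene,protein,NA,NA,loss,FALSE
psbB,gene,protein,NA,NA,loss,FALSE
psbC,gene,protein,NA,NA,loss,FALSE
psbD,gene,protein,NA,NA,loss,FALSE
psbE,gene,protein,NA,NA,loss,FALSE
psbF,gene,protein,NA,NA,loss,FALSE
psbH,gene,protein,NA,NA,loss,FALSE
psbI,gene,protein,NA,NA,loss,FALSE
psbJ,gene,protein,NA,NA,loss,FALSE
psbK,gene,protein,NA,NA,loss,FALSE
psbL,gene,protein,NA,NA,loss,FALSE
psbM,gene,protein,NA,NA,loss,FALSE
psbN,gene,protein,NA,NA,loss,FALSE
psbT,gene,protein,NA,NA,loss,FALSE
psbZ,gene,protein,NA,NA,loss,FALSE
petA,gene,protein,NA,NA,loss,FALSE
petB,gene,protein,NA,NA,loss,FALSE
petD,gene,protein,NA,NA,loss,FALSE
petG,gene,protein,NA,NA,loss,FALSE
petL,gene,protein,NA,NA,loss,FALSE
petN,gene,protein,NA,NA,loss,FALSE
rbcL,gene,protein,NA,NA,loss,FALSE
atpA,gene,protein,NA,NA,loss,FALSE
atpB,gene,protein,NA,NA,loss,FALSE
atpE,gene,protein,NA,NA,loss,FALSE
atpF,gene,protein,NA,NA,loss,FALSE
atpH,gene,protein,NA,NA,loss,FALSE
atpI,gene,protein,NA,NA,loss,FALSE
chlB,gene,protein,NA,NA,loss,FALSE
chlL,gene,protein,NA,NA,loss,FALSE
chlN,gene,protein,NA,NA,loss,FALSE
ndhA,gene,protein,NA,NA,loss,FALSE
ndhB,gene,protein,NA,NA,loss,FALSE
ndhC,gene,protein,NA,NA,loss,FALSE
ndhD,gene,protein,NA,NA,loss,FALSE
ndhE,gene,protein,NA,NA,loss,FALSE
ndhF,gene,protein,NA,NA,loss,FALSE
ndhG,gene,protein,NA,NA,loss,FALSE
ndhH,gene,protein,NA,NA,loss,FALSE
ndhI,gene,protein,NA,NA,loss,FALSE
ndhJ,gene,protein,NA,NA,loss,FALSE
ndhK,gene,protein,NA,NA,loss,FALSE
rpl2,gene,protein,NA,NA,loss,FALSE
rpl14,gene,protein,NA,NA,loss,FALSE
rpl16,gene,protein,NA,NA,loss,FALSE
rpl20,gene,protein,NA,NA,loss,FALSE
rpl21,gene,protein,NA,NA,loss,FALSE
rpl22,gene,protein,NA,NA,loss,FALSE
rpl23,gene,protein,NA,NA,loss,FALSE
rpl32,gene,protein,NA,NA,loss,FALSE
rpl33,gene,protein,NA,NA,loss,FALSE
rpl36,gene,protein,NA,NA,loss,FALSE
rps2,gene,protein,NA,NA,loss,FALSE
rps3,gene,protein,NA,NA,loss,FALSE
rps4,gene,protein,NA,NA,loss,FALSE
rps7,gene,protein,NA,NA,loss,FALSE
rps8,gene,protein,NA,NA,loss,FALSE
rps11,gene,protein,NA,NA,loss,FALSE
rps12,gene,protein,NA,NA,loss,FALSE
rps14,gene,protein,NA,NA,loss,FALSE
rps15,gene,protein,NA,NA,loss,FALSE
rps16,gene,protein,NA,NA,loss,FALSE
rps18,gene,protein,NA,NA,loss,FALSE
rps19,gene,protein,NA,NA,loss,FALSE
rpoA,gene,protein,NA,NA,loss,FALSE
rpoB,gene,protein,NA,NA,loss,FALSE
rpoC1,gene,protein,NA,NA,loss,FALSE
rpoC2,gene,protein,NA,NA,loss,FALSE
infA,gene,protein,NA,NA,loss,FALSE
ccsA,gene,protein,NA,NA,loss,FALSE
matK,gene,protein,NA,NA,loss,FALSE
clpP,gene,protein,NA,NA,loss,FALSE
accD,gene,protein,NA,NA,loss,FALSE
cemA,gene,protein,NA,NA,loss,FALSE
ycf1,gene,protein,NA,NA,loss,FALSE
ycf2,gene,protein,NA,NA,loss,FALSE
ycf3,gene,protein,NA,NA,loss,FALSE
ycf4,gene,protein,NA,NA,loss,FALSE
ycf12,gene,protein,NA,NA,loss,FALSE
ycf66,gene,protein,NA,NA,loss,FALSE
trnAUGCi38,intron,intron,trnA-UGC,38,loss,FALSE
trnGUCCi23,intron,intron,trnG-UCC,23,loss,FALSE
trnIGAUi37,intron,intron,trnI-GAU,37,loss,FALSE
trnKUUUi37,intron,intron,trnK-UUU,37,loss,FALSE
trnLUAAi35,intron,intron,trnL-UAA,35,loss,FALSE
trnVUACi37,intron,intron,trnV-UAC,37,loss,FALSE
atpFi145,intron,intron,atpF,145,loss,FALSE
ndhAi556,intron,intron,ndhA,556,loss,FALSE
ndhBi726,intron,intron,ndhB,726,loss,FALSE
rpl2i397,intron,intron,rpl2,397,loss,FALSE
rpl16i9,intron,intron,rpl16,9,loss,FALSE
rps12i114,intron,intron,rps12,114,loss,TRUE
rps12i346,intron,intron,rps12,346,loss,FALSE
rps16i40,intron,intron,rps16,40,loss,FALSE
rpoC1i432,intron,intron,rpoC1,432,loss,FALSE
petBi6,intron,intron,petB,6,loss,FALSE
petDi8,intron,intron,petD,8,loss,FALSE
clpPi71,intron,intron,clpP,71,loss,FALSE
clpPi363,intron,intron,clpP,363,loss,FALSE
ycf3i124,intron,intron,ycf3,124,loss,FALSE
ycf3i354,intron,intron,ycf3,354,loss,FALSE
ycf66i106,intron,intron,ycf66,106,loss,FALSE
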