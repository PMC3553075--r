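taxon,trnA-UGC,trnC-GCA,trnD-GUC,trnE-UUC,trnF-GAA,trnfM-CAU,trnG-GCC,trnG-UCC,trnH-GUG,trnI-CAU,trnI-GAU,trnK-UUU,trnL-CAA,trnL-UAA,trnL-UAG,trnM-CAU,trnN-GUU,trnP-GGG,trnP-UGG,trnQ-UUG,trnR-ACG,trnR-CCG,trnR-UCU,trnS-CGA,trnS-GCU,trnS-GGA,trnS-UGA,trnT-GGU,trnT-UGU,trnV-GAC,trnV-UAC,trnW-CCA,trnY-GUA,rrn4.5,rrn5,rrn16,rrn23,psaA,psaB,psaC,psaI,psaJ,psaM,psbA,psbB,psbC,psbD,psbE,psbF,psbH,psbI,psbJ,psbK,psbL,psbM,psbN,psbT,psbZ,petA,petB,petD,petG,petL,petN,rbcL,atpA,atpB,atpE,atpF,atpH,atpI,chlB,chlL,chlN,ndhA,ndhB,ndhC,ndhD,ndhE,ndhF,ndhG,ndhH,ndhI,ndhJ,ndhK,rpl2,rpl14,rpl16,rpl20,rpl21,rpl22,rpl23,rpl32,rpl33,rpl36,rps2,rps3,rps4,rps7,rps8,rps11,rps12,rps14,rps15,rps16,rps18,rps19,rpoA,rpoB,rpoC1,rpoC2,infA,ccsA,matK,clpP,accD,cemA,ycf1,ycf2,ycf3,ycf4,ycf12,ycf66,trnAUGCi38,trnGUCCi23,trnIGAUi37,trnKUUUi37,trnLUAAi35,trnVUACi37,atpFi145,ndhAi556,ndhBi726,rpl2i397,rpl16i9,rps12i114,rps12i346,rps16i40,rpoC1i432,petBi6,petDi8,clpPi71,clpPi363,ycf3i124,ycf3i354,ycf66i106
Isoetes_flaccida,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,P,1,1,1,1,1,1,1,1,P,1,1,1,1,1,1,P,1,1,1,P,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,T,1,P,1,1,1,1,1,1,1,1
Huperzia_lucidula,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,0,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,T,1,1,1,1,1,1,1,1,1,1
Ophioglossum_californicum,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1,1,1,1,1,1,T,0,0,1,1,1,1,1,1,1,0
Psilotum_nudum,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,0,0,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1,1,1,1,1,1,T,0,0,1,1,1,1,1,1,1,0
Equisetum_hyemale,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,P,1,1,1,1,1,1,1,1,1,1,0,T,0,0,1,1,1,1,0,1,1,P
Equisetum_arvense,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,P,1,1,1,1,1,1,1,1,1,1,1,T,0,0,1,1,1,1,0,1,1,?
Angiopteris_evecta,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,P,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,T,1,1,1,1,1,1,1,1,1,1
Alsophila_spinulosa,1,1,1,1,1,1,1,1,1,1,1,0,P,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,0,P,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,P,1,1,1,0,1,1,1,1,1,1,1,T,1,1,1,1,1,1,1,1,1,P
Adiantum_capillus_veneris,1,1,1,1,1,1,1,1,1,1,1,0,P,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,0,0,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,0,1,1,1,1,1,1,1,T,1,1,1,1,1,1,1,1,1,0
Pteridium_aquilinum,1,1,1,1,1,1,1,1,1,1,1,0,P,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,0,0,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,0,1,1,1,1,1,1,1,T,1,1,1,1,1,1,1,1,1,0
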