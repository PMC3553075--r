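symbol,kind,class,host,position,direction,trans,genome,state_Isoetes_flaccida,state_Huperzia_lucidula,state_Ophioglossum_californicum,state_Psilotum_nudum,state_Equisetum_hyemale,state_Equisetum_arvense,state_Angiopteris_evecta,state_Alsophila_spinulosa,state_Adiantum_capillus_veneris,state_Pteridium_aquilinum
atp1i361,intron,intron,atp1,361,gain,FALSE,mitochondrial,0,0,0,0,0,0,1,1,1,1
ir_expansion_lsc,structure,structure,NA,NA,gain,FALSE,plastid,0,0,0,1,0,0,1,1,1,1
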