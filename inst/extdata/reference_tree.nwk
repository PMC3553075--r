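((Isoetes_flaccida,Huperzia_lucidula),(((Ophioglossum_californicum,Psilotum_nudum),(Equisetum_hyemale,Equisetum_arvense)),(Angiopteris_evecta,(Alsophila_spinulosa,(Adiantum_capillus_veneris,Pteridium_aquilinum)))));
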