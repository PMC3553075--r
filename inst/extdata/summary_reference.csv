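taxon,accession,size_bp,lsc_bp,ssc_bp,ir_bp,gc_pct,genes,trnas,rrnas,proteins,introns
Isoetes_flaccida,GU191333,145303,91862,27205,13118,37.9,118,32,4,82,21
Huperzia_lucidula,AY660566,154373,104088,19657,15314,36.3,121,31,4,86,22
Ophioglossum_californicum,KC117178,138270,99058,19662,9775,42.2,120,32,4,84,19
Psilotum_nudum,KC117179,138909,84674,16329,18953,36,118,33,4,81,19
Equisetum_hyemale,KC117177,131760,92580,18994,10093,33.7,121,33,4,84,17
Equisetum_arvense,GU191334,133309,93542,19469,10149,33.4,121,33,4,84,18
Angiopteris_evecta,DQ821119,153901,89709,22086,21053,35.5,122,33,4,85,22
Alsophila_spinulosa,FJ556581,156661,86308,21623,24365,40.4,117,28,4,85,20
Adiantum_capillus_veneris,AY178864,150568,82282,21392,23447,42,116,28,4,84,20
Pteridium_aquilinum,HM535629,152362,84335,21259,23384,41.5,116,28,4,84,20
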