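(Daphnia_pulex:510.0,((Japyx_solifugus:300.0,Trigoniophthalmus_alternatus:300.0):185.0,((((Podura_aquatica:225.0,(Bilobella_aurantiaca:170.0,Friesea_grisea:170.0):55.0):55.0,Anurida_maritima:280.0):50.0,(Tullbergia_bisetosa:287.0,(Hypogastrura_viatica:240.0,(Ceratophysella_denticulata:220.0,(Onychiurus_orientalis:192.0,Orthonychiurus_folsomi:192.0):28.0):20.0):47.0):43.0):80.0,(((Neelus_murinus:180.0,Megalothorax_minimus:180.0):160.0,((Allacma_fusca:150.0,Sminthurus_viridis:150.0):140.0,(Bourletiella_arvalis:190.0,Dicyrtomina_ornata:190.0):100.0):50.0):55.0,(((Tomocerus_qinae:90.0,Pogonognathellus_flavescens:90.0):160.0,Oncopodura_yosiiana:250.0):110.0,(((Folsomia_candida:160.0,(Isotoma_viridis:100.0,Desoria_tigrina:100.0):60.0):80.0,(Cryptopygus_antarcticus:190.0,Gomphiocephalus_hodgsoni:190.0):50.0):80.0,((Cyphoderus_albinus:170.0,(Lepidocyrtus_lignorum:140.0,Willowsia_buski:140.0):30.0):110.0,((Salina_celebensis:115.0,Entomobrya_marginata:115.0):115.0,((Orchesella_cincta:60.0,Orchesella_villosa:60.0):90.0,(Sinella_curviseta:110.0,Heteromurus_major:110.0):40.0):80.0):50.0):40.0):40.0):35.0):15.0):75.0):25.0);
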