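taxon	state
Podura_aquatica	aquatic
Bilobella_aurantiaca	hemiedaphic
Friesea_grisea	hemiedaphic
Anurida_maritima	hemiedaphic
Tullbergia_bisetosa	euedaphic
Hypogastrura_viatica	hemiedaphic
Ceratophysella_denticulata	hemiedaphic
Onychiurus_orientalis	euedaphic
Orthonychiurus_folsomi	euedaphic
Neelus_murinus	hemiedaphic
Megalothorax_minimus	hemiedaphic
Allacma_fusca	epiedaphic
Sminthurus_viridis	epiedaphic
Bourletiella_arvalis	epiedaphic
Dicyrtomina_ornata	epiedaphic
Tomocerus_qinae	hemiedaphic
Pogonognathellus_flavescens	hemiedaphic
Oncopodura_yosiiana	hemiedaphic
Folsomia_candida	hemiedaphic
Isotoma_viridis	hemiedaphic
Desoria_tigrina	hemiedaphic
Cryptopygus_antarcticus	hemiedaphic
Gomphiocephalus_hodgsoni	hemiedaphic
Cyphoderus_albinus	myrmecophilous
Lepidocyrtus_lignorum	hemiedaphic
Willowsia_buski	hemiedaphic
Salina_celebensis	epiedaphic
Entomobrya_marginata	hemiedaphic
Orchesella_cincta	hemiedaphic
Orchesella_villosa	hemiedaphic
Sinella_curviseta	hemiedaphic
Heteromurus_major	hemiedaphic
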