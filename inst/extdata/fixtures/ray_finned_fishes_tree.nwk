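(Latimeria_chalumnae,(Polypterus_senegalus,(Lepisosteus_oculatus,(Scleropages_formosus,((Danio_rerio,Astyanax_mexicanus)Otophysi,(Salmo_salar,((Oryzias_latipes,(Xiphophorus_maculatus,Poecilia_formosa)),(Takifugu_rubripes,(Gasterosteus_aculeatus,Oreochromis_niloticus)))Percomorpha))Teleostei)Neopterygii)Actinopterygii));
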