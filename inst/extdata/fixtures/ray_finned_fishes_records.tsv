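species	taxon_group	gene	status	low_confidence	provenance
Latimeria_chalumnae	Coelacanthiformes	CatSper	present	FALSE	curated: the coelacanth conserves all three genes; outgroup for the ray-finned panel
Latimeria_chalumnae	Coelacanthiformes	sNHE	present	FALSE	curated: coelacanth SLC9C is an intact reference in the shared-synteny comparison
Latimeria_chalumnae	Coelacanthiformes	sAC	present	FALSE	curated: the coelacanth conserves all three genes
Polypterus_senegalus	Cladistia	CatSper	present	TRUE	placeholder: one of two unnamed CatSper-conserving ray-finned fishes; early-branching freshwater lineage
Polypterus_senegalus	Cladistia	sNHE	present	TRUE	placeholder: the CatSper-conserving fishes also possess sNHE and sAC
Polypterus_senegalus	Cladistia	sAC	present	TRUE	placeholder: the CatSper-conserving fishes also possess sNHE and sAC
Lepisosteus_oculatus	Holostei	CatSper	present	FALSE	curated: spotted gar is named as carrying SLC9C in the shared-synteny block and counts among the three CatSper-conserving fishes
Lepisosteus_oculatus	Holostei	sNHE	present	FALSE	curated: spotted gar SLC9C appears in the shared-synteny comparison
Lepisosteus_oculatus	Holostei	sAC	present	FALSE	curated: the three CatSper-conserving fishes also possess sNHE and sAC
Scleropages_formosus	Osteoglossomorpha	CatSper	present	TRUE	placeholder: one of two unnamed CatSper-conserving ray-finned fishes; early-branching freshwater lineage
Scleropages_formosus	Osteoglossomorpha	sNHE	present	TRUE	placeholder: the CatSper-conserving fishes also possess sNHE and sAC
Scleropages_formosus	Osteoglossomorpha	sAC	present	TRUE	placeholder: the CatSper-conserving fishes also possess sNHE and sAC
Danio_rerio	Otophysi	CatSper	absent	FALSE	curated: zebrafish is listed among species conserving none of the three genes
Danio_rerio	Otophysi	sNHE	absent	FALSE	curated: zebrafish is listed among species conserving none of the three genes
Danio_rerio	Otophysi	sAC	absent	FALSE	curated: zebrafish is listed among species conserving none of the three genes
Astyanax_mexicanus	Otophysi	CatSper	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Astyanax_mexicanus	Otophysi	sNHE	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Astyanax_mexicanus	Otophysi	sAC	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Salmo_salar	Salmoniformes	CatSper	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Salmo_salar	Salmoniformes	sNHE	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Salmo_salar	Salmoniformes	sAC	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Oryzias_latipes	Percomorpha	CatSper	absent	FALSE	curated: medaka is listed among species conserving none of the three genes
Oryzias_latipes	Percomorpha	sNHE	absent	FALSE	curated: medaka is listed among species conserving none of the three genes
Oryzias_latipes	Percomorpha	sAC	absent	FALSE	curated: medaka is listed among species conserving none of the three genes
Takifugu_rubripes	Percomorpha	CatSper	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Takifugu_rubripes	Percomorpha	sNHE	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Takifugu_rubripes	Percomorpha	sAC	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Gasterosteus_aculeatus	Percomorpha	CatSper	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Gasterosteus_aculeatus	Percomorpha	sNHE	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Gasterosteus_aculeatus	Percomorpha	sAC	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Oreochromis_niloticus	Percomorpha	CatSper	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Oreochromis_niloticus	Percomorpha	sNHE	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Oreochromis_niloticus	Percomorpha	sAC	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Xiphophorus_maculatus	Percomorpha	CatSper	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Xiphophorus_maculatus	Percomorpha	sNHE	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Xiphophorus_maculatus	Percomorpha	sAC	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Poecilia_formosa	Percomorpha	CatSper	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Poecilia_formosa	Percomorpha	sNHE	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
Poecilia_formosa	Percomorpha	sAC	absent	TRUE	placeholder: figure-only teleost; typical teleost pattern of complete loss
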