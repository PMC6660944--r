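species	taxon_group	gene	status	low_confidence	provenance
Mammalia	Mammalia	CatSper	present	FALSE	curated: mammals conserve CatSper, sNHE and sAC (All)
Mammalia	Mammalia	sNHE	present	FALSE	curated: mammals conserve CatSper, sNHE and sAC (All)
Mammalia	Mammalia	sAC	present	FALSE	curated: mammals conserve CatSper, sNHE and sAC (All)
Reptilia	Reptilia	CatSper	present	FALSE	curated: reptiles conserve CatSper, sNHE and sAC (All)
Reptilia	Reptilia	sNHE	present	FALSE	curated: reptiles conserve CatSper, sNHE and sAC (All)
Reptilia	Reptilia	sAC	present	FALSE	curated: reptiles conserve CatSper, sNHE and sAC (All)
Amphibia	Amphibia	CatSper	absent	FALSE	curated: the frog conserves none of the three genes
Amphibia	Amphibia	sNHE	absent	FALSE	curated: the frog conserves none of the three genes
Amphibia	Amphibia	sAC	absent	FALSE	curated: the frog conserves none of the three genes
Coelacanth	Coelacanthiformes	CatSper	present	FALSE	curated: the coelacanth conserves CatSper, sNHE and sAC (All)
Coelacanth	Coelacanthiformes	sNHE	present	FALSE	curated: the coelacanth conserves CatSper, sNHE and sAC (All)
Coelacanth	Coelacanthiformes	sAC	present	FALSE	curated: the coelacanth conserves CatSper, sNHE and sAC (All)
Cartilaginous_fishes	Chondrichthyes	CatSper	present	FALSE	curated: cartilaginous fishes conserve all three genes (All)
Cartilaginous_fishes	Chondrichthyes	sNHE	present	FALSE	curated: cartilaginous fishes conserve all three genes (All)
Cartilaginous_fishes	Chondrichthyes	sAC	present	FALSE	curated: cartilaginous fishes conserve all three genes (All)
Tunicata	Tunicata	CatSper	present	FALSE	curated: tunicates conserve all three genes (All)
Tunicata	Tunicata	sNHE	present	FALSE	curated: tunicates conserve all three genes (All)
Tunicata	Tunicata	sAC	present	FALSE	curated: tunicates conserve all three genes (All)
Amphioxus	Cephalochordata	CatSper	present	FALSE	curated: amphioxus conserves all three genes (All)
Amphioxus	Cephalochordata	sNHE	present	FALSE	curated: amphioxus conserves all three genes (All)
Amphioxus	Cephalochordata	sAC	present	FALSE	curated: amphioxus conserves all three genes (All)
Echinodermata	Echinodermata	CatSper	present	FALSE	curated: echinoderms conserve all three genes (All)
Echinodermata	Echinodermata	sNHE	present	FALSE	curated: echinoderms conserve all three genes (All)
Echinodermata	Echinodermata	sAC	present	FALSE	curated: echinoderms conserve all three genes (All)
Brachiopoda	Brachiopoda	CatSper	present	FALSE	curated: brachiopods conserve all three genes (All)
Brachiopoda	Brachiopoda	sNHE	present	FALSE	curated: brachiopods conserve all three genes (All)
Brachiopoda	Brachiopoda	sAC	present	FALSE	curated: brachiopods conserve all three genes (All)
Mollusca	Mollusca	CatSper	absent	FALSE	curated: molluscs conserve sNHE and sAC without CatSper (Int1)
Mollusca	Mollusca	sNHE	present	FALSE	curated: molluscs conserve sNHE and sAC without CatSper (Int1)
Mollusca	Mollusca	sAC	present	FALSE	curated: molluscs conserve sNHE and sAC without CatSper (Int1)
Trichoplax_adhaerens	Placozoa	CatSper	absent	FALSE	curated: Trichoplax adhaerens conserves only sAC (Int2)
Trichoplax_adhaerens	Placozoa	sNHE	absent	FALSE	curated: Trichoplax adhaerens conserves only sAC (Int2)
Trichoplax_adhaerens	Placozoa	sAC	present	FALSE	curated: Trichoplax adhaerens conserves only sAC (Int2)
Cnidaria	Cnidaria	CatSper	present	FALSE	curated: cnidarians conserve all three genes (All)
Cnidaria	Cnidaria	sNHE	present	FALSE	curated: cnidarians conserve all three genes (All)
Cnidaria	Cnidaria	sAC	present	FALSE	curated: cnidarians conserve all three genes (All)
Ctenophora	Ctenophora	CatSper	present	FALSE	curated: ctenophores conserve all three genes (All)
Ctenophora	Ctenophora	sNHE	present	FALSE	curated: ctenophores conserve all three genes, though the ctenophore VSD is markedly degraded
Ctenophora	Ctenophora	sAC	present	FALSE	curated: ctenophores conserve all three genes (All)
Nematoda	Nematoda	CatSper	absent	TRUE	placeholder: figure-only group; scored as conserving none of the three genes
Nematoda	Nematoda	sNHE	absent	TRUE	placeholder: figure-only group; scored as conserving none of the three genes
Nematoda	Nematoda	sAC	absent	TRUE	placeholder: figure-only group; scored as conserving none of the three genes
Porifera	Porifera	CatSper	absent	TRUE	placeholder: figure-only group; scored as conserving none of the three genes
Porifera	Porifera	sNHE	absent	TRUE	placeholder: figure-only group; scored as conserving none of the three genes
Porifera	Porifera	sAC	absent	TRUE	placeholder: figure-only group; scored as conserving none of the three genes
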