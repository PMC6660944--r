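species	taxon_group	gene	status	low_confidence	provenance
Heliconius_melpomene	Lepidoptera	CatSper	absent	FALSE	curated: this butterfly conserves only two pore-forming alpha subunits instead of four, so it fails the four-subunit rule
Heliconius_melpomene	Lepidoptera	sNHE	present	FALSE	curated: classified Int1, conserving sNHE and sAC without CatSper
Heliconius_melpomene	Lepidoptera	sAC	present	FALSE	curated: classified Int1, conserving sNHE and sAC without CatSper
Danaus_plexippus	Lepidoptera	CatSper	absent	TRUE	placeholder: not individually stated; lepidopterans fall in the Int1 group
Danaus_plexippus	Lepidoptera	sNHE	present	FALSE	curated: monarch SLC9C is an intact reference in the butterfly shared-synteny comparison
Danaus_plexippus	Lepidoptera	sAC	present	TRUE	placeholder: not individually stated; lepidopterans fall in the Int1 group
Bombyx_mori	Lepidoptera	CatSper	absent	TRUE	placeholder: not individually stated; lepidopterans fall in the Int1 group
Bombyx_mori	Lepidoptera	sNHE	present	FALSE	curated: silkworm sNHE is expressed in testis (microarray evidence)
Bombyx_mori	Lepidoptera	sAC	present	FALSE	curated: silkworm sAC is expressed in testis (microarray evidence)
Drosophila_melanogaster	Diptera	CatSper	absent	TRUE	placeholder: not individually stated; the fruit fly retains none of the three intact genes
Drosophila_melanogaster	Diptera	sNHE	pseudogene	FALSE	curated: degraded SLC9C remnant recovered from the non-coding RNA region downstream of FUS
Drosophila_melanogaster	Diptera	sAC	absent	TRUE	placeholder: not individually stated; scored absent
Tribolium_castaneum	Coleoptera	CatSper	absent	TRUE	placeholder: representative of arthropods in which only sAC is conserved (Int2)
Tribolium_castaneum	Coleoptera	sNHE	absent	TRUE	placeholder: representative of arthropods in which only sAC is conserved (Int2)
Tribolium_castaneum	Coleoptera	sAC	present	TRUE	placeholder: representative of arthropods in which only sAC is conserved (Int2)
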