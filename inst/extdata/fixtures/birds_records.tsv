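species	taxon_group	gene	status	low_confidence	provenance
Anolis_carolinensis	Squamata	CatSper	present	FALSE	curated: lizards conserve all three genes and serve as the intact outgroup reference
Anolis_carolinensis	Squamata	sNHE	present	FALSE	curated: lizard SLC9C is the intact reference in the shared-synteny comparison
Anolis_carolinensis	Squamata	sAC	present	FALSE	curated: lizard sAC is the intact reference in the remnant alignments
Apteryx_australis	Palaeognathae	CatSper	present	FALSE	curated: one of only two Palaeognathae birds conserving CatSper
Apteryx_australis	Palaeognathae	sNHE	absent	FALSE	curated: no bird conserves sNHE; kiwi retains CatSper and sAC but not sNHE (Int3)
Apteryx_australis	Palaeognathae	sAC	present	FALSE	curated: kiwi conserves CatSper and sAC but not sNHE (Int3)
Tinamus_guttatus	Palaeognathae	CatSper	present	FALSE	curated: one of only two Palaeognathae birds conserving CatSper
Tinamus_guttatus	Palaeognathae	sNHE	pseudogene	FALSE	curated: degraded SLC9C remnant recovered from the genomic fragment flanked by GAL and PPP6R3
Tinamus_guttatus	Palaeognathae	sAC	present	FALSE	curated: tinamou conserves CatSper and sAC but not sNHE (Int3)
Struthio_camelus	Palaeognathae	CatSper	absent	FALSE	curated: only three intact pore-forming alpha subunits remain, below the four-subunit rule
Struthio_camelus	Palaeognathae	sNHE	absent	FALSE	curated: no bird conserves sNHE
Struthio_camelus	Palaeognathae	sAC	present	TRUE	placeholder: shown in the bird panel without a text statement; scored as conserving sAC
Gallus_gallus	Galloanserae	CatSper	pseudogene	FALSE	curated: chicken CatSper genes degenerated to pseudogenes
Gallus_gallus	Galloanserae	sNHE	absent	FALSE	curated: no bird conserves sNHE
Gallus_gallus	Galloanserae	sAC	present	FALSE	curated: chicken listed among birds in which only sAC is conserved (Int2)
Meleagris_gallopavo	Galloanserae	CatSper	absent	TRUE	placeholder: not individually stated; galliform birds other than the Palaeognathae pair lack CatSper
Meleagris_gallopavo	Galloanserae	sNHE	absent	FALSE	curated: no bird conserves sNHE
Meleagris_gallopavo	Galloanserae	sAC	pseudogene	FALSE	curated: predicted exons encoding an sAC-like protein identify a turkey sAC pseudogene (asterisked)
Anas_platyrhynchos	Galloanserae	CatSper	absent	TRUE	placeholder: not individually stated; only the Palaeognathae pair conserves CatSper
Anas_platyrhynchos	Galloanserae	sNHE	absent	FALSE	curated: no bird conserves sNHE
Anas_platyrhynchos	Galloanserae	sAC	pseudogene	FALSE	curated: predicted exons encoding an sAC-like protein identify a duck sAC pseudogene (asterisked)
Columba_livia	Neoaves	CatSper	absent	TRUE	placeholder: not individually stated; only the Palaeognathae pair conserves CatSper
Columba_livia	Neoaves	sNHE	absent	FALSE	curated: no bird conserves sNHE
Columba_livia	Neoaves	sAC	pseudogene	FALSE	curated: predicted exons encoding an sAC-like protein identify a pigeon sAC pseudogene (asterisked)
Taeniopygia_guttata	Neoaves	CatSper	pseudogene	FALSE	curated: zebra finch CatSper genes degenerated to pseudogenes
Taeniopygia_guttata	Neoaves	sNHE	absent	FALSE	curated: no bird conserves sNHE
Taeniopygia_guttata	Neoaves	sAC	absent	TRUE	placeholder: shown without an asterisk or conservation statement; scored absent
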