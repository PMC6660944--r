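(Ctenophora,(Porifera,(Trichoplax_adhaerens,(Cnidaria,((Nematoda,(Mollusca,Brachiopoda)Lophotrochozoa)Protostomia,(Echinodermata,(Amphioxus,(Tunicata,(Cartilaginous_fishes,(Coelacanth,(Amphibia,(Mammalia,Reptilia)Amniota)Tetrapoda)Sarcopterygii)Gnathostomata)Olfactores)Chordata)Deuterostomia)Bilateria)Eumetazoa)ParaHoxozoa)Planulozoa)Metazoa;
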