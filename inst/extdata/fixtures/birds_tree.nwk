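(Anolis_carolinensis,((Struthio_camelus,(Apteryx_australis,Tinamus_guttatus))Palaeognathae,(((Gallus_gallus,Meleagris_gallopavo)Phasianidae,Anas_platyrhynchos)Galloanserae,(Columba_livia,Taeniopygia_guttata)Neoaves)Neognathae)Aves);
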