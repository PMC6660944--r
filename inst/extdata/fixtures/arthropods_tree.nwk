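(Tribolium_castaneum,(Drosophila_melanogaster,(Bombyx_mori,(Danaus_plexippus,Heliconius_melpomene))Lepidoptera)Mecopterida);
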