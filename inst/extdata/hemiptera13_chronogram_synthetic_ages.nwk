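(((Apis_mellifera:180,Nasonia_vitripennis:180):170,(Tribolium_castaneum:330,(Bombyx_mori:290,(Drosophila_melanogaster:250,Anopheles_gambiae:250):40):40):20):40,(Pediculus_humanus:370,(((Acyrthosiphon_pisum:200,Planococcus_citri:200):50,(Bemisia_tabaci:210,Bactericera_cockerelli:210):40):50,(Diceroprocta_semicincta:260,Rhodnius_prolixus:260):40):70):20);
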