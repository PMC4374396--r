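family	Acyrthosiphon_pisum	Planococcus_citri	Bemisia_tabaci	Bactericera_cockerelli	Diceroprocta_semicincta	Rhodnius_prolixus	Pediculus_humanus	Tribolium_castaneum	Nasonia_vitripennis	Apis_mellifera	Bombyx_mori	Anopheles_gambiae	Drosophila_melanogaster
APC	18	10	12	13	10	7	8	10	10	14	12	9	10
AAAP	22	28	24	25	16	13	16	16	12	14	16	15	17
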