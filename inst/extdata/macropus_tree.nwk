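(Lagostrophus_fasciatus,(Thylogale_thetis,(Lagorchestes_hirsutus,(Onychogalea_unguifera,((Macropus_giganteus,Macropus_fuliginosus),((Macropus_robustus,(Macropus_bernardus,(Macropus_rufus,Macropus_antilopinus))),(Wallabia_bicolor,(Macropus_irma,(Macropus_rufogriseus,(Macropus_agilis,(Macropus_eugenii,Macropus_parma)))))))))));
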