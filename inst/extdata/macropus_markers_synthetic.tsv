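taxon	K01	K02	K03	K04	K05	K06	K07	K08	K09	K10	K11	K12	K13	K14	K15	K16	K17	K18	K19	K20	K21	C1	C2	C3	C4	C5	C6	C7	C8
Macropus_eugenii	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	-
Macropus_parma	+	+	+	+	+	+	+	+	+	+	+	+	+	+	?	?	+	+	+	+	+	+	?	+	+	+	+	+	-
Macropus_agilis	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	-	-	+	+	+	+	+	+	-	-
Macropus_rufogriseus	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	-	-	+	+	+	+	+	-	-	+
Macropus_irma	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	-	-	-
Wallabia_bicolor	-	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	-	-	+	-	-	-	+	+	+	+
Macropus_robustus	-	-	-	-	-	-	-	-	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	-	-	-	-	-
Macropus_bernardus	-	-	-	-	-	-	-	-	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	-	-	-	-	-
Macropus_rufus	-	-	-	-	-	-	-	-	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	-	-	-	-	-
Macropus_antilopinus	-	-	-	-	-	-	-	-	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	-	-	-	-	-
Macropus_giganteus	-	-	-	-	-	-	-	-	-	-	-	+	+	+	+	+	+	+	+	-	-	-	+	-	+	+	-	-	-
Macropus_fuliginosus	-	-	-	-	-	-	-	-	-	-	-	+	+	+	+	+	+	+	+	-	-	-	+	-	+	+	-	-	-
Onychogalea_unguifera	-	-	-	-	-	-	-	-	-	-	-	-	-	-	+	+	+	+	+	-	-	-	-	-	-	-	-	-	-
Lagorchestes_hirsutus	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	+	+	+	+	-	-	-	-	-	-	-	-	-	-
Thylogale_thetis	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	+	+	+	+	-	-	-	-	-	-	-	-	-	-
Lagostrophus_fasciatus	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
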