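reference: Macropus_eugenii
nodes:
  i:
    clade_a: Macropus_irma
    clade_b:
    - Macropus_eugenii
    - Macropus_parma
    - Macropus_agilis
    - Macropus_rufogriseus
    clade_c: Wallabia_bicolor
  ii:
    clade_a: Wallabia_bicolor
    clade_b:
    - Macropus_irma
    - Macropus_eugenii
    - Macropus_parma
    - Macropus_agilis
    - Macropus_rufogriseus
    clade_c:
    - Macropus_robustus
    - Macropus_bernardus
    - Macropus_rufus
    - Macropus_antilopinus
    ratio_clade:
    - Wallabia_bicolor
    - Macropus_irma
    - Macropus_eugenii
    - Macropus_parma
    - Macropus_agilis
    - Macropus_rufogriseus
  iii:
    clade_a: Macropus_irma
    clade_b:
    - Macropus_eugenii
    - Macropus_parma
    - Macropus_agilis
    - Macropus_rufogriseus
    clade_c:
    - Macropus_robustus
    - Macropus_bernardus
    - Macropus_rufus
    - Macropus_antilopinus
    ignore: Wallabia_bicolor
    ratio_clade:
    - Macropus_irma
    - Macropus_eugenii
    - Macropus_parma
    - Macropus_agilis
    - Macropus_rufogriseus
    ratio_within:
    - Wallabia_bicolor
    - Macropus_irma
    - Macropus_eugenii
    - Macropus_parma
    - Macropus_agilis
    - Macropus_rufogriseus
  iv:
    clade_a: Wallabia_bicolor
    clade_b:
    - Macropus_irma
    - Macropus_eugenii
    - Macropus_parma
    - Macropus_agilis
    - Macropus_rufogriseus
    clade_c:
    - Macropus_robustus
    - Macropus_bernardus
    - Macropus_rufus
    - Macropus_antilopinus
    - Macropus_giganteus
    - Macropus_fuliginosus
    ratio_clade:
    - Wallabia_bicolor
    - Macropus_irma
    - Macropus_eugenii
    - Macropus_parma
    - Macropus_agilis
    - Macropus_rufogriseus
    ratio_within:
    - Wallabia_bicolor
    - Macropus_irma
    - Macropus_eugenii
    - Macropus_parma
    - Macropus_agilis
    - Macropus_rufogriseus
    - Macropus_robustus
    - Macropus_bernardus
    - Macropus_rufus
    - Macropus_antilopinus
  v:
    clade_a:
    - Wallabia_bicolor
    - Macropus_irma
    - Macropus_eugenii
    - Macropus_parma
    - Macropus_agilis
    - Macropus_rufogriseus
    clade_b:
    - Macropus_robustus
    - Macropus_bernardus
    - Macropus_rufus
    - Macropus_antilopinus
    clade_c:
    - Macropus_giganteus
    - Macropus_fuliginosus
  vi:
    clade_a:
    - Wallabia_bicolor
    - Macropus_irma
    - Macropus_eugenii
    - Macropus_parma
    - Macropus_agilis
    - Macropus_rufogriseus
    - Macropus_robustus
    - Macropus_bernardus
    - Macropus_rufus
    - Macropus_antilopinus
    clade_b:
    - Macropus_giganteus
    - Macropus_fuliginosus
    clade_c: Onychogalea_unguifera
  vii:
    clade_a:
    - Wallabia_bicolor
    - Macropus_irma
    - Macropus_eugenii
    - Macropus_parma
    - Macropus_agilis
    - Macropus_rufogriseus
    - Macropus_robustus
    - Macropus_bernardus
    - Macropus_rufus
    - Macropus_antilopinus
    - Macropus_giganteus
    - Macropus_fuliginosus
    clade_b: Onychogalea_unguifera
    clade_c: Lagorchestes_hirsutus
  viii:
    clade_a:
    - Wallabia_bicolor
    - Macropus_irma
    - Macropus_eugenii
    - Macropus_parma
    - Macropus_agilis
    - Macropus_rufogriseus
    - Macropus_robustus
    - Macropus_bernardus
    - Macropus_rufus
    - Macropus_antilopinus
    - Macropus_giganteus
    - Macropus_fuliginosus
    - Onychogalea_unguifera
    - Lagorchestes_hirsutus
    clade_b: Thylogale_thetis
    clade_c: Lagostrophus_fasciatus
    ratio_clade:
    - Macropus_eugenii
    - Macropus_parma
    - Macropus_agilis
    - Macropus_rufogriseus
    - Macropus_irma
    - Wallabia_bicolor
    - Macropus_robustus
    - Macropus_bernardus
    - Macropus_rufus
    - Macropus_antilopinus
    - Macropus_giganteus
    - Macropus_fuliginosus
    - Onychogalea_unguifera
    - Lagorchestes_hirsutus
    - Thylogale_thetis
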