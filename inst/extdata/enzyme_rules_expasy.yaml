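# Cleavage-rule table, `expasy` dialect: conventional PeptideCutter-style
# specificities, including the chymotrypsin "not before proline" exception.
# Same grammar as enzyme_rules_milk_panel.yaml.
dialect: expasy
version: 1
enzymes:
  trypsin:
    class: animal
    specs:
      - allow: {P1: KR}
        deny: {P1p: P}
  chymotrypsin:
    class: animal
    specs:
      - allow: {P1: FLMWY}
        deny: {P1p: P}
  pepsin_pH1.3:
    class: animal
    specs:
      - allow: {P1: FL}
        deny: {P3: HKR, P2: P, P1p: P, P2p: P}
      - allow: {P1p: FL}
        deny: {P3: HKR, P2: P, P1: PHKR, P2p: P}
  pepsin_pH>2:
    class: animal
    specs:
      - allow: {P1: FLWY}
        deny: {P3: HKR, P2: P, P1p: P, P2p: P}
      - allow: {P1p: FLWY}
        deny: {P3: HKR, P2: P, P1: PHKR, P2p: P}
  papain:
    class: plant
    specs:
      - allow: {P1: AVLIFWYRK}
        deny: {P1p: P}
  stem_bromelain:
    class: plant
    specs:
      - allow: {P1: RKAYGL}
        deny: {P1p: P}
  subtilisin:
    class: microbial
    specs:
      - allow: {P1: AFILMVWY}
        deny: {P1p: P}
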