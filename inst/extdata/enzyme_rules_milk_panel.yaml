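# Cleavage-rule table, `milk_panel` dialect.
#
# Context grammar: each spec lists allow/deny residue sets at positions
# around the scissile bond (P2 P1 | P1p P2p; P3/P4 also recognized).
# A bond is cut iff at least one spec matches: every `allow` position holds a
# listed residue and no `deny` position does. Positions outside the protein
# never satisfy an `allow` constraint and never violate a `deny` constraint.
#
# Specificities follow the published PeptideCutter/BIOPEP conventions, with
# broad-specificity plant/microbial proteases written as explicit P1 sets.
# In this dialect the chymotrypsin "not before proline" exception is disabled
# (see the stricter `expasy` dialect for the conventional form).
dialect: milk_panel
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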