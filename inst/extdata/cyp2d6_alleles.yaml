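# Default CYP2D6 star-allele definition table.
#
# The 11-variant allelic-discrimination panel and a simplified one-signature-
# per-allele mapping (each non-wild-type allele is recognised by a canonical
# defining variant set; *5 is the whole-gene deletion and is represented by
# copy number, not variant states). Activity classes: EM = fully functional,
# IM = reduced function, PM = non-functional. Replace this file to audit or
# extend the definitions; "*1" (empty defining set) must always be present.
panel_variants:
  - "-1584C>G"
  - "100C>T"
  - "1023C>T"
  - "1707delT"
  - "1846G>A"
  - "2549delA"
  - "2615_2617delAAG"
  - "2851C>T"
  - "2935A>C"
  - "2988G>A"
  - "4181G>C"
alleles:
  - star: "*1"
    activity: EM
    variants: []
  - star: "*2"
    activity: EM
    variants: ["-1584C>G", "2851C>T", "4181G>C"]
  - star: "*3"
    activity: PM
    variants: ["2549delA"]
  - star: "*4"
    activity: PM
    variants: ["1846G>A"]
  - star: "*5"
    activity: PM
    deletion: true
    variants: []
  - star: "*6"
    activity: PM
    variants: ["1707delT"]
  - star: "*7"
    activity: PM
    variants: ["2935A>C"]
  - star: "*9"
    activity: IM
    variants: ["2615_2617delAAG"]
  - star: "*10"
    activity: IM
    variants: ["100C>T"]
  - star: "*17"
    activity: IM
    variants: ["1023C>T", "2851C>T"]
  - star: "*41"
    activity: IM
    variants: ["2988G>A"]
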