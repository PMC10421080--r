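# Default tag and adduct definitions (monoisotopic, Da).
# light_addition: net mass added by one acylation; heavy_addition differs by
# the isotope substitution only. Cationic adduct shifts include electron loss.
# Copy this file and pass it to load_tag_config() to override.
tags:
  - name: propanoyl          # C3H4O added per acylation; heavy = 13C3 H4 O
    light_addition: 56.026214748
    heavy_addition: 59.036279253
    max_tags_per_compound: 3
adducts:
  - name: "H+"
    mass_shift: 1.007276452
    charge: 1
  - name: "Na+"
    mass_shift: 22.989220702
    charge: 1
  - name: "NH4+"
    mass_shift: 18.033825552
    charge: 1
  - name: "none"             # intrinsic cation (e.g. pyridinium), no adduct
    mass_shift: 0.0
    charge: 1
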