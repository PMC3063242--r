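# Default FRT consensus spelled out as a configuration: wild-type bases
# plus the degeneracy tolerated by evolvable Flp variants (R/W/Y IUPAC
# codes at positions 1/-1 and 2/-2).
elements:
  left: GAAGTTCCTATWY
  right: RWATAGGAACTTC
spacer:
  first_base: T
  last_base: A
  max_gc_bases: 4
rules:
  min_proximal8_matches: 5
  min_element_matches_one_side: 5
  min_consecutive_matches: 6
  max_homopolymer_run: 4
  position7_rule: true
  run_in_each_element: false
  forbidden_base_minus1: G
  forbidden_base_plus1: C
weights: 1
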