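name: LacI_operator_part
class: downstream
top_oligo: GATCGGAATTGTGAGCGGATAACAATTCCAGATCTATCGTAA
bottom_oligo: CGCGTTACGATAGATCTGGAATTGTTATCCGCTCACAATTCC
operator_span:
- 5
- 29
regulator:
  name: LacI
  mode: repressor
  inducer: IPTG
spacer: ATCGTAA
carries_promoter_core: no
carries_expression_cassette: no
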