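name: PLuxR_cassette
class: upstream
top_oligo: AATTCTTGACAGCTAGCTCAGTCCTAGGTATAATGCTAGCAAAGAGGAGAAAATGAAAAACATCAACGCCGACGACACCTACCGCATCATCAACAAAATCAAAACCTGCCGCTAATTACCTGTAGGATCGTACAGGTTGTTATAGTCGAATAAATGGTATAATCCGGTATA
bottom_oligo: CTAGTATACCGGATTATACCATTTATTCGACTATAACAACCTGTACGATCCTACAGGTAATTAGCGGCAGGTTTTGATTTTGTTGATGATGCGGTAGGTGTCGTCGGCGTTGATGTTTTTCATTTTCTCCTCTTTGCTAGCATTATACCTAGGACTGAGCTAGCTGTCAAG
operator_span:
- 118
- 137
regulator:
  name: LuxR
  mode: activator
  inducer: AHL
spacer: ''
carries_promoter_core: yes
carries_expression_cassette: yes
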