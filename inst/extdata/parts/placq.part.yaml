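name: Placq
class: upstream
top_oligo: TCGACCGTGACGGATCCTGGTGCAAAACCTTTCGCGGTATGGCATGATAGCGCC
bottom_oligo: GATCGGCGCTATCATGCCATACCGCGAAAGGTTTTGCACCAGGATCCGTCACGG
operator_span: ~
regulator: ~
spacer: ''
carries_promoter_core: yes
carries_expression_cassette: no
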