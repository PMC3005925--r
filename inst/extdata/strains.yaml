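# Host strains and the regulators they express.
# DH5alphaLacI = DH5alpha transformed with a LacI-expressing plasmid.
DH5alphaLacI:
  - LacI
DH5alpha: []
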