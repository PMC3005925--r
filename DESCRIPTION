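Package: cloneBrick
Title: In Silico Restriction Cloning and Standardized Operator-Part Assembly
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates type-II restriction digestion, sticky-end ligation and
    iterative operator-part insertion under a standardized plasmid regulatory
    region (an upstream multi-cloning region plus a BglII/MluI downstream
    standard region), including junction (scar) analysis and the isocaudamer
    trick that regenerates the BglII site after every insertion. Assembled
    regulatory regions are translated into Boolean transcription models so the
    input/output behaviour of a construct (NULL, constitutive, BUFFER, NOT,
    AND, OR) can be derived from its annotations and host strain. Ships a
    synthetic reporter-backbone generator, GenBank/FASTA I/O, a part-library
    format and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    utils,
    stats,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
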