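---
title: "In-silico operator-part assembly and genetic logic"
author: "cloneBrick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico operator-part assembly and genetic logic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneBrick)
```

## The problem

Tuning gene expression in engineered bacteria usually means rebuilding
promoters: adding or exchanging operators — the DNA sites bound by
regulatory proteins — upstream of a reporter or pathway gene. Classical
BioBrick-style standards let parts be chained head-to-tail, but they do not
let a new part be inserted *between* two parts that are already joined,
which is exactly what promoter refactoring needs.

`cloneBrick` models, at single-base resolution, an assembly standard that
solves this with an isocaudamer trick. The regulatory region of a reporter
plasmid is split in two:

* an **upstream multi-cloning region** carrying unique EcoRI, XbaI, SalI and
  BamHI sites, which receives promoter-bearing parts (a strong constitutive
  -35/-10, or an activator cassette with a weak -35/-10), and
* a **downstream standard region** carrying a unique BglII site 5' of a
  unique MluI site, just upstream of the ribosome-binding site, which
  receives operator parts.

A downstream operator part is an annealed oligonucleotide duplex:

```
5'-GATC [operator] AGATCT [spacer]      -3'
3'-     [operator] TCTAGA [spacer] GCGC -5'
```

a BamHI-compatible GATC 5' overhang, the operator, an internal BglII site,
a spacer, and an MluI CGCG 5' overhang. Ligated into the BglII x MluI
opened plasmid, the BamHI-type end seals the BglII cut into a scar that
neither enzyme re-cuts (BamHI/BglII are isocaudamers: different recognition
sequences, identical GATC overhangs), while the part brings its own fresh
BglII site and the MluI joint re-forms ACGCGT. The platform is therefore
*idempotent*: after every insertion the downstream region again has exactly
one BglII and one MluI site, and the next part lands 3' of all previous
ones. Stacking a LacI operator pair under a constitutive promoter gives an
IPTG-inducible device; combining a LuxR activator cassette (AHL input) with
the LacI operator pair gives a two-input genetic AND gate: transcription ON
only when both AHL and IPTG are present.

## The duplex model

Molecules are `DuplexFragment` objects: the fully base-paired core is
stored as its top strand 5'->3' (the bottom strand is always its reverse
complement), and linear molecules carry a `StickyEnd` per terminus — blunt,
or a 5' overhang stored 5'->3' on the protruding strand. Geometry fixes
which strand protrudes: a left 5' overhang is on the top strand, a right 5'
overhang on the bottom strand. 3' overhangs are representable but rejected
by every operation, because no enzyme in scope produces them. Coordinates
are 1-based and inclusive, on the *virtual* top strand (left overhang +
core + top-strand image of the right overhang), the natural convention for
R and the one used by all annotation tables.

Two ends ligate iff both are blunt, or both are 5' overhangs of equal
length whose protruding sequences are mutual reverse complements — for the
4-nt palindromic overhangs of the seven enzymes in scope this reduces to
sequence equality, which is what makes GATC ends from BamHI and BglII (and
CTAG ends from XbaI and SpeI) interchangeable.

## Enzymes and digestion semantics

The seven enzymes (EcoRI, XbaI, SalI, BamHI, BglII, MluI, SpeI) are loaded
from a plain data file (`inst/extdata/enzymes.tsv`), with cut geometries
from the standard REBASE definitions — all palindromic 6-cutters leaving
4-nt 5' overhangs. The table is config-overridable; NotI is deliberately
absent (its site occurs in the backbone but the standard never uses it).

Digestion is complete: every accessible site of every enzyme in the set is
cut; partial digests, star activity, methylation sensitivity and kinetics
are not modelled. Three deliberate semantic choices:

* A recognition span that would reach into a single-stranded overhang of a
  linear fragment is not cut — the enzyme needs duplex DNA.
* Overlapping or immediately adjacent staggered cuts (possible in random
  sequence, e.g. `TCTAGATCT` interleaves XbaI and BglII cuts, and
  `GAATTCTAGA` puts EcoRI and XbaI exactly one overhang apart) cannot both
  fire, because the first cut nicks or single-strands the second site.
  They are resolved greedily 5'->3' with a warning.
* A circular molecule with no site at all is returned unchanged, flagged
  `uncut`, with a warning.

Per-strand nucleotide counts are conserved by construction, and digesting a
circular molecule and re-ligating all fragments reproduces a rotation of
the input; both properties are tested on thousands of random molecules.

## Annealing

`annealOligos()` finds the ungapped antiparallel alignment of two oligos in
which all paired bases are complementary and unpaired bases occur only as
terminal 5' extensions. Alignment is by exact complementarity (no
thermodynamics, no mismatch tolerance — a non-goal). A minimum paired
length of 6 bp is required: shorter pairings are treated as unstable, which
discards the spurious 1–2 bp terminal registers that otherwise make even
the package's own built-in promoter-part oligo pair formally ambiguous. Six
is the smallest value that still admits a 6-bp blunt palindromic duplex.
Among valid alignments the register must be unique; ties are refused rather
than guessed, since a silently chosen register would assemble the wrong
part.

## Two sequence rules the standard needs

Replaying the chemistry exposes two constraints that the part-design
formula alone does not imply; both are enforced by
`designDownstreamPart()` and checked by `validateDownstreamPart()`:

* **The part core must end in A.** In the MluI site ACGCGT, the initial A
  stays with the *discarded* stuffer when the plasmid is opened; the
  retained backbone contributes only `CGCG + T`. The joint re-forms ACGCGT
  only if the last base of the incoming part supplies the A. The built-in
  LacI part's spacer (`ATCGTAA`) does exactly that. Without this rule the
  downstream MluI site is lost and the platform stops being re-insertable.
* **The operator may not begin with T.** The left joint reads
  `...A + GATC + [operator...]`; a leading T would complete AGATCT and
  silently duplicate the BglII site at the scar.

Payloads containing any of the six platform recognition sites (EcoRI, XbaI,
SalI, BamHI, and extra BglII/MluI) are refused by name.

## The promoter-insertion route

The constitutive promoter part has SalI-type (TCGA) and BamHI/BglII-type
(GATC) ends. Opening the platform with SalI + BglII would consume the
downstream BglII site, and the ligation joint (`...GCGCC + GATC + T...`)
contains no AGATCT — under complete-digestion semantics the product can
never be re-cut with BglII, so no further operator insertions are possible.
The full map of the original reporter backbone is not published, so the
package resolves this as its own design decision: `insertUpstream()`
sanctions the pair **(SalI, BamHI)** alongside (SalI, BglII) and
(EcoRI, XbaI), and the reference pipeline installs the promoter via
SalI + BamHI. That route discards only the short SalI–BamHI stuffer,
regenerates the SalI site at the left joint (the part core begins with C),
lets the part-internal GGATCC serve as the region's BamHI, and leaves the
downstream BglII/MluI pair untouched. The (SalI, BglII) route remains
available and a test demonstrates that it destroys the downstream BglII.

Relatedly, `validatePlatform()` treats the four upstream-region site checks
as mandatory only until a promoter part is installed: a promoter insertion
legitimately consumes upstream sites (the XbaI/SpeI scar of the activator
cassette route is re-cuttable by neither enzyme), after which those checks
are reported as `superseded` rather than failing the plasmid. The
downstream checks — exactly one BglII 5' of exactly one MluI inside the
region, none anywhere else, RBS between MluI and the CDS — are always
mandatory.

## Boolean regulatory semantics

The logic layer is qualitative on purpose: the underlying measurements are
ON/OFF reporter outcomes, and no kinetic model is attached (fold-change
prediction is a non-goal). A plasmid's annotations are compiled into a
`RegulatoryModel`: promoter strength class (`strong_constitutive`,
`weak_activator_dependent`, or absent for the promoterless control),
operators 5'->3' with their regulator metadata, and the set of *available*
regulators — host-strain regulators (e.g. the LacI-expressing strain)
unified with plasmid-borne expression cassettes (the LuxR part). Exactly
two regulator archetypes are supported, matching the two induction
mechanisms in scope: a repressor whose inducer releases it (LacI/IPTG) and
an activator whose inducer enables binding (LuxR/AHL); anything else is
rejected loudly.

Evaluation: output is OFF if the promoter is absent; otherwise polymerase
engages iff the core is strong, or weak with its linked activator available
and induced; any repressor-mode operator whose regulator is available but
uninduced silences the region. Operator position (upstream or downstream of
the core) is recorded but does not change the Boolean value — position
matters for construction, not for this logic layer — and tandem copies of
the same operator are idempotent here (copy number is retained for future
quantitative layers). Truth tables enumerate all 2^n inducer combinations
(n <= 8 guard) and are classified as NULL, CONSTITUTIVE, BUFFER, NOT, AND,
OR or OTHER. Two consequences worth noting: both archetypes are activating
in the inducer direction, so adding an inducer can never switch a device
OFF (monotonicity), and adding a repressor operator can only shrink the ON
set; both are property-tested on random models.

## The synthetic backbone

The true reporter backbone sequence is unpublished, so
`buildSyntheticBackbone()` constructs a stand-in from what is known
exactly: the EcoRI site, the engineered upstream multi-cloning region
(reverse complement of the published mutagenesis primer, preserving the
unused NotI site), and the downstream region + RBS + CDS start taken
verbatim from the other published primer
(`GGAGATCT GTCGGATA ACGCGT GAGATTAAAGAGGAGAAATACTAG ATG`). The reporter CDS
body (default 720 nt, GFP-sized) and the origin/marker filler (default
2000 nt, giving a ~2.8 kb plasmid typical of a small reporter vector) are
generated from a seeded RNG and kept free of all seven recognition sites by
per-base rejection (the seven recognitions have pairwise distinct 5-base
prefixes, so a valid base always exists); the assembled circle is then
verified to carry exactly one site for each of the six platform enzymes and
none for SpeI, with a 1000-retry bound on boundary collisions. The same
construction with smaller CDS/filler (120/200 nt) is used for
high-repetition property tests, purely as a problem-size choice.

The LuxR activator cassette is likewise a synthetic stand-in (the real
device's sequence is not available): a constitutive promoter + RBS + short
placeholder *luxR* CDS, the canonical 20-bp lux box as the LuxR operator,
and a weak luxpR-style -35/-10, with EcoRI x SpeI excision end geometry
(core starts with C so EcoRI regenerates on ligation; core ends with A so
the XbaI/SpeI scar is inert). Functions and labels carrying these stand-ins
say "synthetic" explicitly.

What the generator emulates: exact engineered-region sequence, realistic
plasmid size, site uniqueness, determinism per seed. What it does not:
the real backbone's gene content and layout, sequence composition biases,
methylation, and any quantitative expression property. Tests passing on
these fixtures therefore validate the *assembly standard and logic
semantics*, not sequence-level claims about the original plasmids beyond
their printed regions.

## Numerical and degenerate-input choices

* Coordinates 1-based inclusive; circular positions reported in
  [1, length] with the origin fixed at construction; products of
  `insertPart()` are rotated so the upstream region starts at position 1.
* Annealing minimum overlap 6 bp; register ties refused.
* Part orientation during insertion is never guessed: a part compatible in
  zero or two orientations is an error (sticky-end asymmetry GATC vs CGCG
  normally forces uniqueness).
* A backbone with more than one site for a named insertion enzyme is
  refused — the standard guarantees uniqueness, so duplication means a
  malformed platform.
* Junction scar windows are 8 bp (4-nt overhang + 2 bp context each side),
  sufficient to detect every 6-bp site in scope.
* Features split by a cut are kept as truncated pieces and re-merged into
  single region annotations after insertion; a feature landing across a
  ligation origin is kept as two truncated pieces.
* Only the designed single-insert product is returned; self-ligation,
  concatemers and vector re-closure are real side-products but out of
  scope.

## Problem sizes used by the test suite

The acceptance-style checks run 100 trials of 10 sequential random-part
insertions on the compact platform; oracle equivalence on 500 random 2-kb
sequences in both topologies against all seven enzymes (1000 molecules);
500 random design/anneal/validate round trips; and byte-level determinism
of the full pipeline at a fixed seed. `scripts/acceptance.R` recomputes the
same families of quantities at moderated sizes and writes them as JSON.

## Known limitations

* No thermodynamics anywhere: annealing, ligation efficiency and digestion
  kinetics are exact/boolean.
* Boolean outputs only; the measured fold-changes of the original
  constructs are wet-lab quantities with no computational counterpart here.
* Only palindromic type-II enzymes with 5' overhangs; no type-IIS, no
  3'-overhang or blunt cutters beyond the blunt-end ligation primitive.
* The backbone and the activator cassette are synthetic stand-ins; only
  their printed regions are sequence-faithful.
* The GenBank dialect is minimal (LOCUS/COMMENT/FEATURES/ORIGIN with
  misc_feature qualifiers); it round-trips everything the package writes
  but is not a general GenBank parser.
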