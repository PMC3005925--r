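# cloneBrick

In-silico restriction cloning and standardized operator-part assembly for
genetic logic design.

## The problem

Refactoring a bacterial promoter — adding operator sites so that repressors
(LacI, released by IPTG) or activators (LuxR, enabled by AHL) control a
gene — normally requires bespoke cloning for every variant. Head-to-tail
part standards (BioBricks) cannot insert a part *between* two parts that
are already joined. `cloneBrick` models, exactly and at single-base
resolution, an assembly standard built on an isocaudamer trick that makes
such insertions repeatable, and derives the Boolean logic of what was
assembled. It is aimed at synthetic biologists planning constructs and at
anyone who wants an executable, testable model of sticky-end cloning.

## The core mechanism

The reporter plasmid's regulatory region is standardized into an upstream
multi-cloning region (unique EcoRI, XbaI, SalI, BamHI sites — receives
promoter parts) and a downstream standard region (unique BglII site 5' of a
unique MluI site, just upstream of the RBS — receives operator parts). A
downstream operator part is an annealed duplex

```
top    = GATC + operator + AGATCT + spacer
bottom = CGCG + revcomp(operator + AGATCT + spacer)
```

i.e. a BamHI-compatible GATC 5' overhang, the operator, an internal BglII
site and an MluI CGCG overhang. BamHI (G^GATCC) and BglII (A^GATCT) are
isocaudamers: different recognition sites, identical GATC overhangs. Ligated
between the plasmid's BglII and MluI cuts, the part's left joint becomes a
scar neither enzyme recuts, the part's own AGATCT becomes the new BglII
site, and the MluI joint regenerates ACGCGT — so the insertion can be
repeated indefinitely, each operator landing 3' of the previous one.
Stacking two LacI operators downstream of a LuxR activator cassette yields
a regulatory region that transcribes only when both AHL and IPTG are
present: a genetic AND gate.

The package implements: exact duplex/sticky-end algebra, oligo annealing,
double-strand motif search, complete digestion by the seven standard
enzymes (REBASE geometries, config-overridable), ligation with junction
(scar) analysis, part design/validation, platform validation, high-level
`insertUpstream()`/`insertDownstream()` operations, Boolean regulatory
models with truth-table enumeration and gate classification, a seeded
synthetic reporter backbone, GenBank/FASTA/YAML I/O and a CLI.

## Worked example

```r
library(cloneBrick)

lacOperatorPart()
#> OperatorPart 'LacI_operator_part' (downstream class, 46 nt)
#>   regulator: LacI (repressor, inducer IPTG)

res <- makeAndGate(strain = "DH5alphaLacI", seed = 1)
res$tables[["PLuxR-LacItandem-GFP"]]
#> TruthTable over {AHL, IPTG} -- gate: AND
#>   none                 OFF
#>   AHL                  OFF
#>   IPTG                 OFF
#>   AHL+IPTG             ON

p <- res$plasmids[["PLuxR-LacItandem-GFP"]]
fragmentLength(p)
#> [1] 3026
downstreamRegionSeq(p)
#> [1] "GGAGATCGGAATTGTGAGCGGATAACAATTCCAGATCGGAATTGTGAGCGGATAACAATTCCAGATCTATCGTAACGCGT"
```

`makeAndGate()` builds six constructs by simulated digestion/ligation only
— the promoterless backbone, the constitutive control, single and tandem
LacI-operator insertions, the LuxR construct, and the AND gate — validates
each against the platform standard, and derives its truth table under the
chosen host strain. The downstream-region string above shows the mechanism
directly: the first LacI operator's BglII site was sealed into the inert
`AGATCG` scar, the second part brought the fresh `AGATCT`, and the MluI
site `ACGCGT` was rebuilt at the right joint. In strain `DH5alpha`
(no LacI), the same plasmid is ON whenever AHL is present — the repressor
layer is inert without its protein.

The same operations are scriptable from a shell:

```sh
Rscript inst/scripts/clonebrick fixture make-and-gate --strain DH5alphaLacI --seed 1
Rscript inst/scripts/clonebrick digest --enzymes BglII,MluI --in plasmid.gb --out frags.fa
Rscript inst/scripts/clonebrick simulate --plasmid product.gb --strain DH5alphaLacI --format json
```

## Package layout

- `R/` — duplex model, restriction engine, assembly, part standard,
  regulatory logic, backbone generator, I/O, CLI
- `inst/extdata/` — enzyme table, strain table
- `tests/testthat/` — unit, property and end-to-end suites with
  independent oracles
- `vignettes/operator-part-assembly.Rmd` — the methods vignette: model
  assumptions, the two sequence rules the standard needs, the
  promoter-insertion route decision, numerical choices and limitations
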