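---
title: "Methods: batch knockout and tagging primer design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: batch knockout and tagging primer design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primedesign)
```

## The construct and the primer geometry

Yeast gene deletion and C-terminal tagging both start from a PCR product
amplified off a pFA6a-series template vector. The primers carry two parts:
a genomic *homology arm* of N bases that directs integration by homologous
recombination, and a constant 3' *priming site* that anneals to the
vector. The arm geometry depends on the feature type:

* **CDS deletion, forward**: the N−3 bases upstream of the start codon
  followed by the start codon itself. The arm always ends in the sense
  `ATG`, so recombination removes the ORF from its first codon onward.
* **CDS tagging, forward**: the N sense bases immediately 5' of the stop
  codon (the final triplet of the annotated span). The tag integrates in
  frame directly before the stop; the tag cassette supplies its own stop.
* **Reverse (shared)**: reverse complement of the stop codon plus the
  N−3 bases downstream. Deletion and tagging cassettes share this primer.
* **Non-coding features** (ncRNA, tRNA, 3'UTR): plain N bases upstream
  (forward) and the reverse complement of N bases downstream (reverse);
  there is no codon bookkeeping and no tagging primer.

All geometry is expressed in *sense space*: "upstream" means 5' of the
feature in its direction of transcription, and minus-strand features read
the reverse complement of the plus strand. Coordinates are 1-based
inclusive from parse to output — the primer table echoes the annotation's
coordinates unchanged, which keeps the whole pipeline on a single
convention and avoids off-by-one drift.

Constant tails are fixed sequences: forward `CGGATCCCCGGGTTAATTAA`
(20 nt) and reverse `GAATTCGAGCTCGTTTAAAC` (20 nt) prime the pFA6a
multi-cloning site; deleting a 3'UTR instead uses the 21-nt
`GCGAATTTCTTATGATTTATG` forward tail, which amplifies the adh1 terminator
so the upstream gene retains termination after its UTR is replaced. Tails
always sit at the 3' end of the long primer (homology 5', priming site
3'), matching how the primer must extend across the cassette during PCR.
They can be overridden through the configuration file, but never
silently: any non-canonical tail is reported when the tail set is built.

## Tunable parameters

| parameter | units | default | rationale |
|---|---|---|---|
| `homology_length` (N) | bases | 80 (pombe preset), 50 (cerevisiae presets) | organism conventions for efficient recombination; overridable per run |
| `end_region_len` | bases | 30 | width of the 5'/3' check-file regions; enough to identify a locus in a browser without bloating the file |
| tails | DNA | pFA6a constants above | only overridden explicitly, with a message |
| `type_aliases` | GFF3 type strings | none | opt-in; e.g. treat `pseudogene` and transposable-element types as genes on CDS runs |

N is validated ≥ 4: the CDS rules place N−3 genomic bases in the forward
arm, so smaller N degenerates. The homology width is an absolute
contract — arms are never silently truncated. A feature running past a
chromosome end gets the missing positions as literal `N` characters, on
both ends symmetrically, so every untailed arm is exactly N wide; padded
primers are still reported (the user can see the padding and decide).

## From annotation to catalog

A run catalogues one target per feature. Annotation lines of the matching
GFF3 type are grouped by their `Parent` attribute (falling back to `ID`),
and each group becomes a single feature spanning `min(start)..max(end)`:

* **Intron-containing genes** are designed on their genomic envelope, not
  spliced coordinates — a deletion cassette replaces the whole locus, and
  the C-terminal arm is drawn from genomic sense context even if an
  intron lies within N bases of the stop. This is logged territory for
  unusual gene models rather than something the package tries to repair.
* **Multi-transcript genes** must yield exactly one primer row. The
  transcript whose identifier sorts first lexicographically is used and
  the siblings are dropped with a note; the shared gene identifier
  becomes the systematic name. Lexicographic order is the one tie-break
  that is deterministic across annotation sources without knowing their
  transcript-naming conventions.
* **Features without orientation** (strand `.` or `?`) are skipped with a
  warning: primer geometry is undefined without a transcription
  direction.
* The annotated span is **assumed to include the stop codon**. Rather
  than repairing violations, `validate_feature()` reports them as notes
  (`no_ATG_start`, `no_stop_end`) and primers are designed regardless —
  pseudogenes included via an alias legitimately lack these conventions,
  and the user, not the software, should judge them.

For 3'UTR deletion the forward homology is taken as the N bases
immediately upstream of the UTR start on the sense strand — the same rule
as every other non-coding feature — combined with the adh1-terminator
tail. The choice of homology geometry for UTRs was genuinely open; the
uniform non-coding rule was chosen because it leaves the upstream CDS
stop codon intact and requires no UTR-specific bookkeeping.

## Overlap reporting

Deleting a span in a compact genome can clip a neighbour. The report
lists, for each target, every CDS or ncRNA on the same chromosome whose
span intersects the target span (closed intervals; adjacency is not
overlap). Two deliberate choices:

* **Span only, not span + arms**: the cassette physically replaces
  exactly the feature span; the homology arms are regenerated by
  recombination, so sequence under the arms is not lost.
* **Strand-agnostic**: an antisense ncRNA is destroyed by the deletion
  regardless of which strand it is read from.

All neighbours are reported, joined with `;` — no fixed cap — so no
disruption is ever hidden by column budgeting. Batch computation goes
through `GenomicRanges::findOverlaps`; the test suite checks it against a
quadratic all-pairs scan and a per-target filter, and checks the symmetry
property (A disrupts B iff B disrupts A).

## The synthetic-genome generator

Real genome releases are external downloads, so all testing runs on
seeded synthetic genomes. `generate_synthetic_genome()` plants features
with known sequence on a uniform-random A/C/G/T background and always
includes the structurally awkward cases: a gene starting at position 1 of
a chromosome and another ending flush at a chromosome end (exercising
`N`-padding), a minus-strand CDS, a two-segment CDS (exercising envelope
merging), a nested overlapping CDS pair (the inner gene overwrites only
its host's interior, so both keep valid start/stop codons), and ncRNA,
tRNA and 3'UTR features. Planted CDSs are `ATG` + random codons + stop by
construction. Generation is fully deterministic given the spec's seed,
and an infeasible plan (a nested gene too large for its host) is a
generation error rather than a silently corrupted fixture.

Each fixture carries a truth table of expected primers computed by a
brute-force oracle written independently of the primer engine: it
N-pads the chromosome string and uses plain `substr` arithmetic, and
handles minus-strand features by reverse-complementing the whole
chromosome and mirroring coordinates — a different indexing path from the
engine's sense-window computation, so shared bugs are unlikely.

What the generator does **not** emulate: realistic yeast base
composition or GC content, intron statistics, ambiguity codes from
resequenced strains, or annotation dialect quirks beyond standard GFF3.
Passing tests therefore demonstrate the geometric and parsing rules, not
robustness to every real-world annotation file; the GFF3 parser accepts
the standard dialect only, and adapters for nonstandard tabular dialects
are left to the user.

The default test problem sizes are a 12-feature fixture for unit tests
and a 500-feature, multi-chromosome fixture (both strands, all feature
types, overlapping and end-abutting cases) for the oracle-equivalence and
geometry checks, each evaluated at N ∈ {4, 6, 50, 80} — small enough to
run quickly, large enough that every structural case appears many times.

## Numerical and degenerate-input behaviour

There is no randomness anywhere in the design path; the fixture
generator is the only seeded component, and identical inputs produce
byte-identical output files (the legacy integer CLI and the flag CLI
resolve to the same configuration and are compared byte-for-byte in the
tests). Degenerate inputs behave as follows: an empty but well-formed
annotation yields a complete three-file run with zero data rows; a
feature shorter than the check-file end region reports its full sequence
as both end regions; a CDS shorter than N+3 draws its tagging arm from
upstream genomic context; duplicate systematic names abort before
anything is written; and all computation happens before any file is
opened, so a fatal parse or validation error leaves no partial primer
table behind.

## Known limitations

* No melting-temperature optimisation, primer-dimer or off-target
  screening — arms are purely positional, as the recombination protocol
  assumes.
* No N-terminal tagging or promoter-replacement primers.
* Spliced-coordinate tagging across introns is not supported (genomic
  envelope only).
* GFF2/GTF and compressed inputs are not supported.
* The canonical output is tab-delimited text; it imports into a
  spreadsheet directly, and no native spreadsheet file is written.
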