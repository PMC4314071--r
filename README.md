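# primedesign

Batch design of the long PCR primers used to delete or C-terminally tag
genomic features in fission (*Schizosaccharomyces pombe*) and budding
(*Saccharomyces cerevisiae*) yeast by homologous recombination.

## The problem and the method

In yeast, a gene is deleted or tagged by transforming cells with a
PCR-generated cassette — a selectable marker (and, for tagging, an epitope
tag) amplified from a pFA6a-series template vector — flanked by short
regions of homology to the target locus. Each long primer is therefore a
concatenation of

```
5'  [ homology arm: N genomic bases ] [ constant vector priming site ]  3'
```

with N = 80 bp for *S. pombe* and 50 bp for *S. cerevisiae* by convention.
Designing these by hand is mechanical but error-prone, and genome-wide
studies need thousands of them. `primedesign` automates the whole batch:
given a genome FASTA and its GFF3 annotation it designs, for every feature
of a requested type (CDS, ncRNA, 3'UTR or tRNA):

- **forward deletion primer** — for a CDS, the start codon `ATG` plus the
  N−3 bases upstream of it (so the arm always ends in the sense `ATG`);
  for non-coding features, the N bases upstream of the feature;
- **forward C-terminal tagging primer** (CDS only) — the N sense bases
  immediately 5' of the stop codon, so a tag fuses in frame just before
  the stop;
- **reverse primer** — shared by both constructs: the reverse complement
  of (stop codon + N−3 downstream bases) for a CDS, or of the N bases
  downstream of the feature end otherwise.

Each arm is reported untailed and with its constant 3' priming site: the
20-mer `CGGATCCCCGGGTTAATTAA` (forward, pFA6a multi-cloning site), the
20-mer `GAATTCGAGCTCGTTTAAAC` (reverse), or the 21-mer
`GCGAATTTCTTATGATTTATG` (forward tail for 3'UTR deletion, which amplifies
the adh1 terminator so the gene keeps transcriptional termination).
Features running off a chromosome end get `N`-padded arms of the exact
same width. Because yeast genomes are compact, the output also lists every
neighbouring CDS/ncRNA whose span intersects a deletion — deletions that
would clip a neighbour are flagged with the neighbour names and count.

## Worked example

```r
library(primedesign)

genome <- c(chr1 = "ACGTACGTATGAAATAGTTGGCCAA")   # toy: CDS at 9..17 is ATGAAATAG
feat <- data.frame(systematic_name = "g1", common_name = "abc1",
                   chrom_id = "chr1", start = 9L, end = 17L, strand = "+",
                   ftype = "CDS")
t(design_primers(feat, genome, design_params(6, "CDS")))
#> systematic_name "g1"
#> common_name     "abc1"
#> chrom_id        "chr1"
#> start           "9"
#> end             "17"
#> strand          "+"
#> fwd_del         "CGTATG"
#> fwd_del_tailed  "CGTATGCGGATCCCCGGGTTAATTAA"
#> fwd_tag         "ATGAAA"
#> fwd_tag_tailed  "ATGAAACGGATCCCCGGGTTAATTAA"
#> rev             "CAACTA"
#> rev_tailed      "CAACTAGAATTCGAGCTCGTTTAAAC"
#> overlap_names   ""
#> overlap_count   "0"
```

With N = 6 the forward deletion arm is the 3 bases upstream of the gene
(`CGT`) plus the start codon; the tagging arm `ATGAAA` is the last two
sense codons before the stop; the reverse arm is the reverse complement of
the stop codon `TAG` plus the 3 downstream bases `TTG`. The tailed
versions append the constant pFA6a priming sites.

Whole-genome runs use the command-line wrapper (legacy integer form or
flags — both produce byte-identical output):

```sh
# genome 0 = pombe preset (file paths from the config), feature 1 = CDS, N = 80
Rscript inst/scripts/design-primers.R 0 1 80 --config genomes.conf

Rscript inst/scripts/design-primers.R design \
  --genome genome.fa --annotation genome.gff3 \
  --feature cds --homology 80 --out mygenome_cds
```

Every run writes three tab-delimited, spreadsheet-importable files:
`<out>.header.txt` (genome label, chromosome names and lengths, feature
count, column schema), `<out>.primers.tsv` (one row per feature: names,
coordinates, strand, all primers, overlap columns) and `<out>.check.tsv`
(5'/3' end regions and full sense sequence of each feature, for manual
verification in a genome browser).

Because genome releases are external downloads, no genome is bundled;
`generate_synthetic_genome()` builds seeded synthetic FASTA/GFF3 pairs
with a brute-force truth table for testing and demonstration.

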