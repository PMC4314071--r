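# Hand-checkable toy genome used across test files:
#   chr1 positions 1-25: ACGTACGTATGAAATAGTTGGCCAA ; CDS+ at 9-17, sense ATGAAATAG
#   chr2 positions 1-25: ACGTACGTTTAGGGCATTTGGCCAA ; CDS- at 9-17, sense ATGCCCTAA
toy_genome <- c(chr1 = "ACGTACGTATGAAATAGTTGGCCAA",
                chr2 = "ACGTACGTTTAGGGCATTTGGCCAA")

toy_feature <- function(name = "g1", chrom = "chr1", start = 9L, end = 17L,
                        strand = "+", ftype = "CDS", common = "") {
  data.frame(systematic_name = name, common_name = common, chrom_id = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = strand, ftype = ftype, stringsAsFactors = FALSE)
}

toy_cds_plus <- toy_feature("g1", "chr1", 9, 17, "+")
toy_cds_minus <- toy_feature("g2", "chr2", 9, 17, "-")

# One shared 12-feature synthetic genome (written to disk once per run).
.fixture_cache <- new.env(parent = emptyenv())
shared_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    dir <- file.path(tempdir(), "primedesign-fixture12")
    .fixture_cache$fx <- suppressMessages(generate_synthetic_genome(
      synthetic_genome_spec(seed = 424242L, n_features = 12L), dir = dir))
  }
  .fixture_cache$fx
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
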