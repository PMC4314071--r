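# The primer geometry rules on hand-checkable toys, plus the engine's
# structural properties.

test_that("sense flanks are stranded and chromosome-end padded", {
  expect_identical(sense_flank(toy_genome, toy_cds_plus, "upstream", 3), "CGT")
  expect_identical(sense_flank(toy_genome, toy_cds_minus, "upstream", 3), "CAA")
  expect_identical(sense_flank(toy_genome, toy_cds_plus, "downstream", 3), "TTG")
  # feature at position 1: empty upstream context is all N
  at_start <- toy_feature("gs", "chr1", 1, 9, "+")
  expect_identical(sense_flank(toy_genome, at_start, "upstream", 7), "NNNNNNN")
  # partial padding: 2 genomic bases available, rest N
  near_start <- toy_feature("gn", "chr1", 3, 9, "+")
  expect_identical(sense_flank(toy_genome, near_start, "upstream", 5), "NNNAC")
  # zero-length flank is empty
  expect_identical(sense_flank(toy_genome, toy_cds_plus, "upstream", 0), "")
  expect_error(sense_flank(toy_genome, toy_feature(chrom = "chrX"), "upstream", 3),
               "unknown chromosome")
})

test_that("reverse complement is a validated Watson-Crick involution", {
  expect_identical(revcomp("ACGT"), "ACGT")   # palindrome
  expect_identical(revcomp(""), "")
  expect_identical(revcomp("TAGTTG"), "CAACTA")
  expect_identical(revcomp("NAN"), "NTN")
  expect_error(revcomp("ACXGT"), "position 3")
  # involution and length preservation over random sequences
  set.seed(7)
  for (len in c(1L, 5L, 33L, 200L)) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE),
               collapse = "")
    expect_identical(revcomp(revcomp(s)), s)
    expect_identical(nchar(revcomp(s)), len)
  }
})

test_that("deletion forward primers follow the CDS and non-coding rules", {
  p6 <- design_params(6, "CDS")
  expect_identical(design_deletion_forward(toy_cds_plus, toy_genome, p6), "CGTATG")
  expect_identical(design_deletion_forward(toy_cds_minus, toy_genome, p6), "CAAATG")
  # the same span treated as non-coding takes plain upstream homology
  nc <- toy_feature("n1", "chr1", 9, 17, "+", ftype = "ncRNA")
  expect_identical(design_deletion_forward(nc, toy_genome, design_params(6, "ncRNA")),
                   "GTACGT")
})

test_that("C-terminal tagging primers end at the last sense codon before the stop", {
  p6 <- design_params(6, "CDS")
  expect_identical(design_ctag_forward(toy_cds_plus, toy_genome, p6), "ATGAAA")
  expect_identical(design_ctag_forward(toy_cds_minus, toy_genome, p6), "ATGCCC")
  # arm + stop codon reconstitutes the sense 3' end of the CDS
  sense <- feature_sequence(toy_genome, toy_cds_plus)
  arm <- design_ctag_forward(toy_cds_plus, toy_genome, p6)
  expect_identical(paste0(arm, substr(sense, nchar(sense) - 2, nchar(sense))),
                   substring(sense, nchar(sense) - 8))
  # CDS shorter than N+3: the arm reaches into upstream genomic context
  p8 <- design_params(8, "CDS")
  expect_identical(design_ctag_forward(toy_cds_plus, toy_genome, p8), "GTATGAAA")
  expect_error(design_ctag_forward(nc <- toy_feature(ftype = "ncRNA"),
                                   toy_genome, design_params(6, "ncRNA")),
               "CDS")
})

test_that("reverse primers are shared by deletion and tagging geometries", {
  p6c <- design_params(6, "CDS")
  expect_identical(design_reverse(toy_cds_plus, toy_genome, p6c), "CAACTA")
  # minus-strand reverse equals a plus-strand substring: strand consistency
  expect_identical(design_reverse(toy_cds_minus, toy_genome, p6c),
                   substr(toy_genome[["chr2"]], 6, 11))
  expect_identical(design_reverse(toy_cds_minus, toy_genome, p6c), "CGTTTA")
  p6n <- design_params(6, "ncRNA")
  expect_identical(design_reverse(toy_cds_plus, toy_genome, p6n), "GGCCAA")
})

test_that("constant tails attach at the 3' end and are the pFA6a sequences", {
  tails <- pfa6a_tails()
  expect_identical(attach_tail("CGTATG", "fwd_standard", tails),
                   "CGTATGCGGATCCCCGGGTTAATTAA")
  expect_identical(attach_tail("CAACTA", "rev", tails),
                   "CAACTAGAATTCGAGCTCGTTTAAAC")
  expect_identical(attach_tail("GTACGT", "fwd_utr", tails),
                   "GTACGTGCGAATTTCTTATGATTTATG")
  expect_error(attach_tail("", "rev", tails), "non-empty")
  # overriding a tail is possible but loud
  expect_message(custom <- pfa6a_tails(fwd_tail = "AAAA"), "non-standard")
  expect_identical(attach_tail("CGTATG", "fwd_standard", custom), "CGTATGAAAA")
  expect_error(pfa6a_tails(fwd_tail = "ACGU"), "\\{A,C,G,T\\}")
})

test_that("homology length is an absolute contract, padding included", {
  fx <- shared_fixture()
  genome <- fx$genome
  feats <- fx$features
  for (nn in c(4L, 50L)) {
    for (i in seq_len(nrow(feats))) {
      f <- toy_feature(feats$systematic_name[i], feats$chrom_id[i],
                       feats$start[i], feats$end[i], feats$strand[i],
                       feats$type[i])
      params <- design_params(nn, feats$type[i])
      expect_identical(nchar(design_deletion_forward(f, genome, params)), nn)
      expect_identical(nchar(design_reverse(f, genome, params)), nn)
      if (feats$type[i] == "CDS") {
        expect_identical(nchar(design_ctag_forward(f, genome, params)), nn)
      }
    }
  }
  # the gene at position 1 of chr1 carries N-padding in its forward arm
  g1 <- feats[feats$start == 1L & feats$chrom_id == "chr1", ][1, ]
  fwd <- design_deletion_forward(
    toy_feature(g1$systematic_name, g1$chrom_id, g1$start, g1$end,
                g1$strand, g1$type),
    genome, design_params(50, g1$type))
  expect_identical(substr(fwd, 1, 47), strrep("N", 47))
})

test_that("strand duality: mirrored minus-strand designs match", {
  fx <- shared_fixture()
  for (i in which(fx$features$type == "CDS")[1:4]) {
    f <- fx$features[i, ]
    chrom <- fx$genome[[f$chrom_id]]
    len <- nchar(chrom)
    mirrored_genome <- stats::setNames(revcomp(chrom), f$chrom_id)
    mirrored <- toy_feature(f$systematic_name, f$chrom_id,
                            len - f$end + 1L, len - f$start + 1L,
                            if (f$strand == "+") "-" else "+", f$type)
    orig <- toy_feature(f$systematic_name, f$chrom_id, f$start, f$end,
                        f$strand, f$type)
    p <- design_params(30, "CDS")
    expect_identical(design_deletion_forward(orig, fx$genome, p),
                     design_deletion_forward(mirrored, mirrored_genome, p))
    expect_identical(design_reverse(orig, fx$genome, p),
                     design_reverse(mirrored, mirrored_genome, p))
    expect_identical(design_ctag_forward(orig, fx$genome, p),
                     design_ctag_forward(mirrored, mirrored_genome, p))
  }
})

test_that("design parameters are validated", {
  expect_error(design_params(3, "CDS"), ">= 4")
  expect_error(design_params(80, "exon"), "unknown feature type")
  expect_identical(design_params(80, "cds")$ftype, "CDS")
  expect_identical(design_params("50", "3'UTR")$ftype, "3UTR")
})
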