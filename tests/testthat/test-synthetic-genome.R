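# The seeded fixture generator and its independent brute-force oracle.

test_that("generation is deterministic for a given spec", {
  spec <- synthetic_genome_spec(seed = 99L, n_features = 10L)
  a <- generate_synthetic_genome(spec)
  b <- generate_synthetic_genome(spec)
  expect_identical(a$fasta_lines, b$fasta_lines)
  expect_identical(a$gff3_lines, b$gff3_lines)
  expect_identical(a$truth, b$truth)
  # a different seed gives a different genome
  c <- generate_synthetic_genome(synthetic_genome_spec(seed = 100L,
                                                       n_features = 10L))
  expect_false(identical(a$fasta_lines, c$fasta_lines))
})

test_that("the plan accounting and structural cases are all present", {
  fx <- shared_fixture()
  plan <- fx$features
  expect_identical(nrow(plan), 12L)
  # one parent group per planted feature
  rec <- read_gff3(fx$paths$gff3)
  key <- ifelse(is.na(rec$Parent), rec$ID, rec$Parent)
  expect_identical(length(unique(key)), 12L)
  # both strands, a gene at position 1, a two-segment CDS, a nested pair
  expect_setequal(unique(plan$strand), c("+", "-"))
  expect_true(any(plan$start == 1L & plan$chrom_id == "chr1"))
  expect_true(any(plan$segments == 2L))
  host <- plan[4, ]
  inner <- plan[5, ]
  expect_true(inner$start > host$start + 3L && inner$end < host$end - 3L)
  # a feature flush against the chr1 end
  expect_true(any(plan$end[plan$chrom_id == "chr1"] ==
                    nchar(fx$genome[["chr1"]])))
  # every planted CDS is ATG ... stop on its sense strand, by construction
  cds <- plan[plan$type == "CDS", ]
  expect_true(all(substr(cds$sense_seq, 1, 3) == "ATG"))
  expect_true(all(substr(cds$sense_seq, nchar(cds$sense_seq) - 2,
                         nchar(cds$sense_seq)) %in% c("TAA", "TAG", "TGA")))
  # all four feature types are represented
  expect_setequal(unique(plan$type), c("CDS", "ncRNA", "3UTR", "tRNA"))
})

test_that("an infeasible nested plant raises a generation error", {
  spec <- synthetic_genome_spec(seed = 5L, n_features = 8L,
                                nested_inner_codons = 10000L)
  expect_error(generate_synthetic_genome(spec), "infeasible plan")
})

test_that("engine primers equal the oracle truth table on the shared fixture", {
  fx <- shared_fixture()
  genome <- read_genome_fasta(fx$paths$fasta)
  rec <- read_gff3(fx$paths$gff3)
  universe <- rbind(suppressMessages(build_catalog(rec, "CDS")),
                    suppressMessages(build_catalog(rec, "ncRNA")))
  for (code in c("CDS", "ncRNA", "3UTR", "tRNA")) {
    catalog <- suppressMessages(build_catalog(rec, code))
    for (nn in unique(fx$truth$homology_length)) {
      got <- design_primers(catalog, genome, design_params(nn, code),
                            universe = universe)
      want <- fx$truth[fx$truth$ftype == code & fx$truth$homology_length == nn, ]
      want <- want[match(got$systematic_name, want$systematic_name), ]
      expect_identical(got$fwd_del, want$fwd_del)
      expect_identical(got$rev, want$rev)
      expect_identical(got$fwd_del_tailed, want$fwd_del_tailed)
      expect_identical(got$rev_tailed, want$rev_tailed)
      if (code == "CDS") {
        expect_identical(got$fwd_tag, want$fwd_tag)
        expect_identical(got$fwd_tag_tailed, want$fwd_tag_tailed)
      }
      expect_identical(got$overlap_count, want$overlap_count)
      expect_identical(got$overlap_names, want$overlap_names)
    }
  }
})

test_that("end-abutting features pad with exactly the predicted number of Ns", {
  fx <- shared_fixture()
  genome <- fx$genome
  plan <- fx$features
  n <- 50L
  # gene at position 1: CDS forward arm has N-3 padded positions upstream
  first <- plan[plan$start == 1L & plan$chrom_id == "chr1", ][1, ]
  f <- data.frame(systematic_name = first$systematic_name,
                  common_name = "", chrom_id = first$chrom_id,
                  start = first$start, end = first$end,
                  strand = first$strand, ftype = first$type,
                  stringsAsFactors = FALSE)
  fwd <- design_deletion_forward(f, genome, design_params(n, first$type))
  expected_pad <- if (first$type == "CDS") n - 3L else n
  expect_identical(substr(fwd, 1, expected_pad), strrep("N", expected_pad))
  expect_false(substr(fwd, expected_pad + 1L, expected_pad + 1L) == "N")
  # feature flush at the chr1 end: downstream flank is entirely N
  flush <- plan[plan$chrom_id == "chr1" &
                  plan$end == nchar(genome[["chr1"]]), ][1, ]
  ff <- data.frame(systematic_name = flush$systematic_name, common_name = "",
                   chrom_id = flush$chrom_id, start = flush$start,
                   end = flush$end, strand = flush$strand,
                   ftype = flush$type, stringsAsFactors = FALSE)
  side <- if (flush$strand == "+") "downstream" else "upstream"
  expect_identical(sense_flank(genome, ff, side, 20L), strrep("N", 20L))
})
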