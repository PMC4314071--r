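# Seeded synthetic genome + annotation generator with a machine-readable
# truth table, so the whole pipeline is testable without downloading a real
# genome. The expected primers in the truth table come from a brute-force
# oracle written independently of the primer engine: it never shares
# helpers with the engine, and for minus-strand features it works on the
# reverse-complemented chromosome with mirrored coordinates instead of
# taking sense windows on the plus strand.

# ---- independent brute-force oracle -----------------------------------

.ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(x) {
  if (!nzchar(x)) return("")
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  paste(rev(unname(.ORACLE_COMP[chars])), collapse = "")
}

#' Brute-force expected primers for one feature
#'
#' Reference computation used to populate synthetic-genome truth tables:
#' the chromosome is N-padded on both sides so plain \code{substr} indexing
#' applies, and minus-strand features are handled by reverse-complementing
#' the whole chromosome and mirroring the coordinates. Deliberately naive
#' and independent of the primer engine.
#'
#' @param chrom_seq Chromosome sequence (character scalar).
#' @param start,end 1-based inclusive feature span.
#' @param strand \code{"+"} or \code{"-"}.
#' @param ftype Feature code.
#' @param n Homology length N.
#' @return List with \code{fwd_del}, \code{fwd_tag} (NA unless CDS) and
#'   \code{rev}, all untailed.
#' @export
oracle_primers <- function(chrom_seq, start, end, strand, ftype, n) {
  if (strand == "-") {
    len <- nchar(chrom_seq)
    chrom_seq <- oracle_revcomp(chrom_seq)
    s <- len - end + 1L
    e <- len - start + 1L
  } else {
    s <- start
    e <- end
  }
  pad <- strrep("N", n + 3L)
  p <- paste0(pad, chrom_seq, pad)
  off <- nchar(pad)
  if (ftype == "CDS") {
    fwd <- paste0(substr(p, off + s - (n - 3L), off + s - 1L),
                  substr(p, off + s, off + s + 2L))
    tag <- substr(p, off + e - 2L - n, off + e - 3L)
    rev <- oracle_revcomp(substr(p, off + e - 2L, off + e + n - 3L))
  } else {
    fwd <- substr(p, off + s - n, off + s - 1L)
    tag <- NA_character_
    rev <- oracle_revcomp(substr(p, off + e + 1L, off + e + n))
  }
  list(fwd_del = fwd, fwd_tag = tag, rev = rev)
}

# All-pairs disrupted-neighbour scan (quadratic, oracle-side).
oracle_overlap_scan <- function(features, universe) {
  out <- data.frame(systematic_name = features$systematic_name,
                    overlap_names = character(nrow(features)),
                    overlap_count = integer(nrow(features)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(features))) {
    nbs <- character(0L)
    starts <- integer(0L)
    for (j in seq_len(nrow(universe))) {
      if (universe$systematic_name[[j]] == features$systematic_name[[i]]) next
      if (universe$chrom_id[[j]] != features$chrom_id[[i]]) next
      if (universe$start[[j]] <= features$end[[i]] &&
          universe$end[[j]] >= features$start[[i]]) {
        nbs <- c(nbs, universe$systematic_name[[j]])
        starts <- c(starts, universe$start[[j]])
      }
    }
    ord <- order(starts, nbs)
    out$overlap_names[[i]] <- paste(nbs[ord], collapse = ";")
    out$overlap_count[[i]] <- length(nbs)
  }
  out
}

# ---- fixture specification --------------------------------------------

#' Specification of a synthetic test genome
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @param n_features Number of planted features (>= 8, so that every
#'   structural case — plus- and minus-strand CDSs, a multi-segment CDS, an
#'   overlapping nested pair, a gene flush against each chromosome end, and
#'   noncoding features — is represented).
#' @param homology_lengths N values at which the truth table's expected
#'   primers are computed.
#' @param features_per_chrom Packing density; controls the chromosome count.
#' @param nested_inner_codons Codon count of the nested overlap partner, or
#'   NULL to draw it; a value too large to fit inside its host is an
#'   infeasible plan and raises a generation error.
#' @return A list of class \code{fixture_spec}.
#' @export
synthetic_genome_spec <- function(seed = 20260922L, n_features = 12L,
                                  homology_lengths = c(4L, 6L, 50L, 80L),
                                  features_per_chrom = 80L,
                                  nested_inner_codons = NULL) {
  n_features <- as.integer(n_features)
  if (is.na(n_features) || n_features < 8L) {
    stop("n_features must be >= 8", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_features = n_features,
                 homology_lengths = as.integer(homology_lengths),
                 features_per_chrom = as.integer(features_per_chrom),
                 nested_inner_codons = nested_inner_codons),
            class = "fixture_spec")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.random_orf <- function(codons) {
  stopifnot(codons >= 3L)
  paste0("ATG", .random_dna(3L * (codons - 2L)),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

#' Generate a synthetic genome, annotation and truth table
#'
#' Builds a deterministic FASTA/GFF3 pair with planted features whose
#' correct primers are known by construction. The plan always includes: a
#' CDS starting at position 1 of chromosome 1, a two-segment CDS (its
#' deletion span is the genomic envelope), a minus-strand CDS, a nested
#' overlapping CDS pair (the inner gene overwrites only the interior of its
#' host, so both keep their start and stop codons), a CDS ending flush at
#' the chromosome 1 end, and ncRNA / tRNA / 3'UTR features; remaining
#' features are drawn randomly over types and strands. Planted CDS sense
#' sequences always begin \code{ATG} and end in a stop codon. The truth
#' table carries, per feature and per homology length, the expected
#' untailed and tailed primers from the brute-force oracle plus all-pairs
#' overlap columns (universe = CDS + ncRNA).
#'
#' @param spec A \code{\link{synthetic_genome_spec}}.
#' @param dir Optional directory; when given, \code{genome.fa},
#'   \code{annotation.gff3} and \code{truth.tsv} are written there.
#' @return List with \code{genome} (named character vector),
#'   \code{fasta_lines}, \code{gff3_lines}, \code{features} (the planted
#'   plan with systematic names as the catalog will report them),
#'   \code{truth} (per feature x N expected primers), and \code{paths}
#'   (when \code{dir} was given).
#' @export
generate_synthetic_genome <- function(spec = synthetic_genome_spec(),
                                      dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, .generate_synthetic_genome_impl(spec, dir))
}

.generate_synthetic_genome_impl <- function(spec, dir) {
  n <- spec$n_features
  per_chrom <- max(spec$features_per_chrom, 8L)
  # Feature plan. Special slots (all on chr1): 1 = CDS+ at position 1,
  # 2 = two-segment CDS, 3 = minus-strand CDS, 4 = nested-pair host,
  # 5 = nested inner CDS (planted inside 4), 6 = ncRNA, 7 = tRNA,
  # 8 = 3'UTR; the last feature placed on chr1 ends flush at its end.
  types <- character(n)
  types[1:5] <- "CDS"
  types[6:8] <- c("ncRNA", "tRNA", "3UTR")
  if (n > 8L) {
    types[9:n] <- sample(c("CDS", "ncRNA", "tRNA", "3UTR"), n - 8L,
                         replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1))
  }
  strands <- sample(c("+", "-"), n, replace = TRUE)
  strands[[1L]] <- "+"
  strands[[3L]] <- "-"

  plan <- data.frame(idx = seq_len(n), type = types, strand = strands,
                     chrom_id = NA_character_, start = NA_integer_,
                     end = NA_integer_, sense_len = NA_integer_,
                     segments = 1L, common_name = NA_character_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    plan$sense_len[[i]] <- if (types[[i]] == "CDS") {
      codons <- if (i %in% c(2L, 4L)) sample(30:60, 1L) else sample(8:40, 1L)
      3L * codons
    } else {
      sample(60:200, 1L)
    }
  }
  plan$segments[[2L]] <- 2L
  plan$common_name <- ifelse(stats::runif(n) < 0.3,
                             paste0("cn", seq_len(n)), NA_character_)

  # Sequential placement (slot 5, the nested gene, is placed inside slot 4
  # afterwards and occupies no slot of its own on the chromosome walk).
  placed <- setdiff(seq_len(n), 5L)
  n_chrom <- max(2L, ceiling(length(placed) / per_chrom))
  chrom_of <- rep(seq_len(n_chrom), each = ceiling(length(placed) / n_chrom))
  chrom_ids <- paste0("chr", seq_len(n_chrom))
  cursor <- stats::setNames(rep(0L, n_chrom), chrom_ids)
  for (k in seq_along(placed)) {
    i <- placed[[k]]
    cid <- chrom_ids[[min(chrom_of[[k]], n_chrom)]]
    gap <- if (i == 1L) 0L else sample(30:120, 1L)
    plan$chrom_id[[i]] <- cid
    plan$start[[i]] <- cursor[[cid]] + gap + 1L
    plan$end[[i]] <- plan$start[[i]] + plan$sense_len[[i]] - 1L
    cursor[[cid]] <- plan$end[[i]]
  }
  # Nested inner gene: strictly inside its host, clear of the host's start
  # and stop codons.
  host <- plan[4L, ]
  inner_max_codons <- (host$sense_len - 18L) %/% 3L
  inner_codons <- if (is.null(spec$nested_inner_codons)) {
    sample(3:min(20L, inner_max_codons), 1L)
  } else as.integer(spec$nested_inner_codons)
  if (inner_codons < 3L || inner_codons > inner_max_codons) {
    stop(sprintf("infeasible plan: nested gene of %d codons cannot fit inside its %d bp host",
                 inner_codons, host$sense_len), call. = FALSE)
  }
  plan$sense_len[[5L]] <- 3L * inner_codons
  plan$chrom_id[[5L]] <- host$chrom_id
  slack <- host$sense_len - 18L - plan$sense_len[[5L]]
  offset <- if (slack > 0L) sample(0:slack, 1L) else 0L
  plan$start[[5L]] <- host$start + 9L + offset
  plan$end[[5L]] <- plan$start[[5L]] + plan$sense_len[[5L]] - 1L

  # Chromosome lengths: random tail, except chr1 where the last placed
  # feature ends flush at the chromosome end.
  chrom_len <- stats::setNames(integer(n_chrom), chrom_ids)
  for (cid in chrom_ids) {
    tail_len <- if (cid == "chr1") 0L else sample(50:150, 1L)
    chrom_len[[cid]] <- cursor[[cid]] + tail_len
  }

  # Background sequence, then plant features (nested gene last so it
  # overwrites only its host's interior).
  genome <- stats::setNames(vapply(chrom_len, .random_dna, character(1L)),
                            chrom_ids)
  plant_order <- c(setdiff(seq_len(n), 5L), 5L)
  sense_seqs <- character(n)
  for (i in plant_order) {
    sense <- if (plan$type[[i]] == "CDS") {
      .random_orf(plan$sense_len[[i]] %/% 3L)
    } else {
      .random_dna(plan$sense_len[[i]])
    }
    sense_seqs[[i]] <- sense
    planted <- if (plan$strand[[i]] == "+") sense else oracle_revcomp(sense)
    substr(genome[[plan$chrom_id[[i]]]], plan$start[[i]], plan$end[[i]]) <- planted
  }
  # The nested plant rewrote its host's interior; refresh stored senses.
  for (i in seq_len(n)) {
    raw <- substr(genome[[plan$chrom_id[[i]]]], plan$start[[i]], plan$end[[i]])
    sense_seqs[[i]] <- if (plan$strand[[i]] == "+") raw else oracle_revcomp(raw)
    if (plan$type[[i]] == "CDS") {
      sl <- nchar(sense_seqs[[i]])
      if (substr(sense_seqs[[i]], 1L, 3L) != "ATG" ||
          !substr(sense_seqs[[i]], sl - 2L, sl) %in% c("TAA", "TAG", "TGA")) {
        stop("infeasible plan: planting destroyed the start or stop codon of feature ",
             i, call. = FALSE)
      }
    }
  }

  # Systematic names as the catalog will report them (CDS lines carry
  # Parent = <gene>.1, single transcript, so the transcript id is kept).
  plan$systematic_name <- ifelse(
    plan$type == "CDS", paste0("gene", plan$idx, ".1"),
    paste0(c(CDS = "gene", ncRNA = "ncrna", tRNA = "trna", `3UTR` = "utr")[plan$type],
           plan$idx))
  plan$sense_seq <- sense_seqs

  gff3 <- c("##gff-version 3")
  for (i in seq_len(n)) {
    name_attr <- if (!is.na(plan$common_name[[i]])) {
      paste0(";Name=", plan$common_name[[i]])
    } else ""
    if (plan$type[[i]] == "CDS") {
      tr <- paste0("gene", plan$idx[[i]], ".1")
      if (plan$segments[[i]] == 2L) {
        p <- plan$start[[i]] + plan$sense_len[[i]] %/% 3L
        q <- p + 21L
        stopifnot(q < plan$end[[i]])
        segs <- rbind(c(plan$start[[i]], p), c(q, plan$end[[i]]))
      } else {
        segs <- rbind(c(plan$start[[i]], plan$end[[i]]))
      }
      for (s in seq_len(nrow(segs))) {
        gff3 <- c(gff3, paste(plan$chrom_id[[i]], "synthetic", "CDS",
                              segs[s, 1L], segs[s, 2L], ".", plan$strand[[i]],
                              "0", paste0("ID=", tr, ":", s, ";Parent=", tr,
                                          name_attr),
                              sep = "\t"))
      }
    } else {
      gtype <- c(ncRNA = "ncRNA", tRNA = "tRNA", `3UTR` = "three_prime_UTR")[[plan$type[[i]]]]
      gff3 <- c(gff3, paste(plan$chrom_id[[i]], "synthetic", gtype,
                            plan$start[[i]], plan$end[[i]], ".",
                            plan$strand[[i]], ".",
                            paste0("ID=", plan$systematic_name[[i]], name_attr),
                            sep = "\t"))
    }
  }

  fasta <- unlist(lapply(chrom_ids, function(cid) {
    body <- genome[[cid]]
    starts <- seq(1L, nchar(body), by = 60L)
    c(paste0(">", cid, " synthetic length=", nchar(body)),
      substring(body, starts, pmin(starts + 59L, nchar(body))))
  }))

  # Truth table: expected primers per feature per N, via the oracle.
  universe <- plan[plan$type %in% c("CDS", "ncRNA"),
                   c("systematic_name", "chrom_id", "start", "end"),
                   drop = FALSE]
  ov <- oracle_overlap_scan(
    plan[, c("systematic_name", "chrom_id", "start", "end"), drop = FALSE],
    universe)
  truth <- do.call(rbind, lapply(spec$homology_lengths, function(nn) {
    rows <- lapply(seq_len(n), function(i) {
      pr <- oracle_primers(genome[[plan$chrom_id[[i]]]], plan$start[[i]],
                           plan$end[[i]], plan$strand[[i]], plan$type[[i]], nn)
      fwd_tail <- if (plan$type[[i]] == "3UTR") "GCGAATTTCTTATGATTTATG" else "CGGATCCCCGGGTTAATTAA"
      data.frame(systematic_name = plan$systematic_name[[i]],
                 ftype = plan$type[[i]], chrom_id = plan$chrom_id[[i]],
                 start = plan$start[[i]], end = plan$end[[i]],
                 strand = plan$strand[[i]], homology_length = nn,
                 fwd_del = pr$fwd_del,
                 fwd_del_tailed = paste0(pr$fwd_del, fwd_tail),
                 fwd_tag = pr$fwd_tag,
                 fwd_tag_tailed = ifelse(is.na(pr$fwd_tag), NA_character_,
                                         paste0(pr$fwd_tag, "CGGATCCCCGGGTTAATTAA")),
                 rev = pr$rev,
                 rev_tailed = paste0(pr$rev, "GAATTCGAGCTCGTTTAAAC"),
                 overlap_names = ov$overlap_names[[i]],
                 overlap_count = ov$overlap_count[[i]],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  rownames(truth) <- NULL

  out <- list(genome = genome, fasta_lines = fasta, gff3_lines = gff3,
              features = plan, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "genome.fa"),
                  gff3 = file.path(dir, "annotation.gff3"),
                  truth = file.path(dir, "truth.tsv"))
    writeLines(fasta, paths$fasta)
    writeLines(gff3, paths$gff3)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}
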