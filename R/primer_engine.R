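# The primer-design rules: stranded flank extraction with chromosome-end
# padding, reverse complement, the three primer geometries, constant tails.

# Canonical pFA6a priming-site constants. The forward and reverse 20-mers
# hybridise to the multi-cloning site flanking the insert; the 21-mer
# amplifies the adh1 terminator and replaces the standard forward tail when
# deleting a 3'UTR (the gene must keep a terminator).
.PFA6A_FWD_TAIL <- "CGGATCCCCGGGTTAATTAA"
.PFA6A_REV_TAIL <- "GAATTCGAGCTCGTTTAAAC"
.PFA6A_UTR_FWD_TAIL <- "GCGAATTTCTTATGATTTATG"

#' Constant pFA6a priming-site tails
#'
#' The three constant 3' extensions appended to the homology arms:
#' \code{fwd_tail} (20 nt) and \code{rev_tail} (20 nt) prime the
#' multi-cloning site of pFA6a-series vectors; \code{utr_fwd_tail} (21 nt)
#' primes the adh1 terminator, used as the forward tail when deleting
#' 3'UTRs. Overriding a tail is possible but deliberately loud: any
#' non-canonical sequence is reported with a message, so a database built
#' with modified priming sites is never produced silently.
#'
#' @param fwd_tail,rev_tail,utr_fwd_tail Tail sequences (DNA text).
#' @return A named list of class \code{tail_set}.
#' @export
pfa6a_tails <- function(fwd_tail = .PFA6A_FWD_TAIL,
                        rev_tail = .PFA6A_REV_TAIL,
                        utr_fwd_tail = .PFA6A_UTR_FWD_TAIL) {
  tails <- list(fwd_tail = toupper(fwd_tail), rev_tail = toupper(rev_tail),
                utr_fwd_tail = toupper(utr_fwd_tail))
  for (nm in names(tails)) {
    t <- tails[[nm]]
    if (!nzchar(t) || grepl("[^ACGT]", t)) {
      stop("tail ", nm, " must be non-empty DNA over {A,C,G,T}", call. = FALSE)
    }
  }
  canonical <- c(fwd_tail = .PFA6A_FWD_TAIL, rev_tail = .PFA6A_REV_TAIL,
                 utr_fwd_tail = .PFA6A_UTR_FWD_TAIL)
  for (nm in names(canonical)) {
    if (tails[[nm]] != canonical[[nm]]) {
      message(sprintf("non-standard %s in use: %s (canonical pFA6a site is %s)",
                      nm, tails[[nm]], canonical[[nm]]))
    }
  }
  structure(tails, class = "tail_set")
}

#' Design parameters for one batch run
#'
#' @param homology_length Homology-arm length N in bases. Must be >= 4: the
#'   CDS forward arm is built from N-3 upstream bases plus the start codon,
#'   so smaller N leaves no genomic homology. Defaults follow the organism
#'   conventions for efficient homologous recombination: 80 bp for
#'   S. pombe, 50 bp for S. cerevisiae (see \code{\link{genome_presets}}).
#' @param ftype Feature code: \code{"CDS"}, \code{"ncRNA"}, \code{"3UTR"} or
#'   \code{"tRNA"}.
#' @param tailed Whether tailed primer versions are wanted (both tailed and
#'   untailed are always reported in the table; this flag is kept on the
#'   params for callers that only need arms).
#' @return A list of class \code{design_params}.
#' @export
design_params <- function(homology_length, ftype, tailed = TRUE) {
  n <- as.integer(homology_length)
  if (is.na(n) || n < 4L) {
    stop("homology_length must be an integer >= 4 (got ",
         homology_length, ")", call. = FALSE)
  }
  structure(list(homology_length = n, ftype = normalize_ftype(ftype),
                 tailed = isTRUE(tailed)),
            class = "design_params")
}

# Genome as a named character vector of uppercase sequences, the internal
# representation used for substring extraction.
.genome_chars <- function(genome) {
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome character vector must be named")
    return(toupper(genome))
  }
  stats::setNames(as.character(genome), names(genome))
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick reverse complement (an involution). \code{N} maps
#' to \code{N}; IUPAC ambiguity codes are complemented so that flanks drawn
#' from resequenced genomes survive. Any other character is a fatal error
#' reporting its position.
#'
#' @param seq Character vector of DNA strings (may be empty strings).
#' @return Character vector of the same length and element widths.
#' @export
revcomp <- function(seq) {
  bad <- regexpr("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[[1L]]
    stop(sprintf("cannot reverse-complement '%s': unsupported character '%s' at position %d",
                 seq[[i]], substr(seq[[i]], bad[[i]], bad[[i]]), bad[[i]]),
         call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Plus-strand substring of a chromosome over a closed interval, padding any
# positions beyond either chromosome end with 'N'. Zero-width intervals
# (to < from) return "".
.padded_plus_segment <- function(chrom_seq, from, to) {
  if (to < from) return("")
  len <- nchar(chrom_seq)
  left_pad <- max(0L, min(to, 0L) - from + 1L)     # positions < 1
  right_pad <- max(0L, to - max(len, from - 1L))   # positions > len
  core_from <- max(from, 1L)
  core_to <- min(to, len)
  core <- if (core_from <= core_to) substr(chrom_seq, core_from, core_to) else ""
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}

# Window of the feature's sense strand, addressed in sense coordinates:
# position 1 is the feature's first transcribed base, position L its last;
# positions < 1 reach upstream, > L downstream. Minus-strand features read
# the reverse complement of the plus strand. Positions beyond either
# chromosome end are 'N'.
.sense_window <- function(chrom_seq, start, end, strand, from, to) {
  if (strand == "+") {
    seg <- .padded_plus_segment(chrom_seq, start + from - 1L, start + to - 1L)
    seg
  } else {
    seg <- .padded_plus_segment(chrom_seq, end - to + 1L, end - from + 1L)
    if (nzchar(seg)) revcomp(seg) else seg
  }
}

.feature_fields <- function(feature) {
  list(chrom = as.character(feature$chrom_id), start = as.integer(feature$start),
       end = as.integer(feature$end), strand = as.character(feature$strand))
}

.chrom_seq_of <- function(genome_chars, chrom) {
  if (!chrom %in% names(genome_chars)) {
    stop("unknown chromosome: ", chrom, call. = FALSE)
  }
  genome_chars[[chrom]]
}

#' Flanking sequence of a feature, in sense orientation
#'
#' Returns exactly \code{len} bases of genomic sequence 5' (upstream) or 3'
#' (downstream) of the feature in its direction of transcription. For
#' minus-strand features the plus-strand segment is reverse-complemented.
#' Positions beyond a chromosome end are filled with \code{N}, so the
#' returned width is always \code{len}.
#'
#' @param genome Genome (\code{DNAStringSet} or named character vector).
#' @param feature One catalog row.
#' @param side \code{"upstream"} or \code{"downstream"} (in sense space).
#' @param len Number of bases (>= 0).
#' @return A DNA string of width \code{len}.
#' @export
sense_flank <- function(genome, feature, side = c("upstream", "downstream"), len) {
  side <- match.arg(side)
  len <- as.integer(len)
  if (is.na(len) || len < 0L) stop("len must be >= 0", call. = FALSE)
  g <- .genome_chars(genome)
  f <- .feature_fields(feature)
  chrom_seq <- .chrom_seq_of(g, f$chrom)
  feat_len <- f$end - f$start + 1L
  if (side == "upstream") {
    .sense_window(chrom_seq, f$start, f$end, f$strand, 1L - len, 0L)
  } else {
    .sense_window(chrom_seq, f$start, f$end, f$strand, feat_len + 1L, feat_len + len)
  }
}

#' Sense-strand sequence of a feature
#'
#' @param genome Genome (\code{DNAStringSet} or named character vector).
#' @param feature One catalog row.
#' @return The feature's transcribed-orientation sequence.
#' @export
feature_sequence <- function(genome, feature) {
  g <- .genome_chars(genome)
  f <- .feature_fields(feature)
  chrom_seq <- .chrom_seq_of(g, f$chrom)
  .sense_window(chrom_seq, f$start, f$end, f$strand, 1L, f$end - f$start + 1L)
}

#' Forward deletion primer (homology arm)
#'
#' For a CDS the arm is the N-3 bases upstream of the start codon plus the
#' start codon itself, so the primer always ends in the sense \code{ATG}.
#' For non-coding features (ncRNA, 3'UTR, tRNA) it is simply the N bases
#' upstream of the feature. Width is exactly N in every case, chromosome
#' ends included (missing positions are \code{N}-padded).
#'
#' @param feature One catalog row.
#' @param genome Genome.
#' @param params \code{\link{design_params}}.
#' @return Untailed homology arm of width \code{N}.
#' @export
design_deletion_forward <- function(feature, genome, params) {
  n <- params$homology_length
  if (params$ftype == "CDS") {
    g <- .genome_chars(genome)
    f <- .feature_fields(feature)
    chrom_seq <- .chrom_seq_of(g, f$chrom)
    paste0(.sense_window(chrom_seq, f$start, f$end, f$strand, 4L - n, 0L),
           .sense_window(chrom_seq, f$start, f$end, f$strand, 1L, 3L))
  } else {
    sense_flank(genome, feature, "upstream", n)
  }
}

#' Forward C-terminal tagging primer (homology arm)
#'
#' The N sense bases immediately 5' of the stop codon (the final triplet of
#' the CDS span), so that a tag amplified with this primer fuses in frame
#' just before the stop. When the CDS is shorter than N+3 the arm extends
#' upstream of the feature into genomic sense context (no padding unless a
#' chromosome end is crossed).
#'
#' @inheritParams design_deletion_forward
#' @return Untailed homology arm of width \code{N}.
#' @export
design_ctag_forward <- function(feature, genome, params) {
  if (params$ftype != "CDS") {
    stop("C-terminal tagging primers are defined for CDS features only",
         call. = FALSE)
  }
  n <- params$homology_length
  g <- .genome_chars(genome)
  f <- .feature_fields(feature)
  chrom_seq <- .chrom_seq_of(g, f$chrom)
  feat_len <- f$end - f$start + 1L
  .sense_window(chrom_seq, f$start, f$end, f$strand,
                feat_len - 2L - n, feat_len - 3L)
}

#' Reverse primer (homology arm)
#'
#' Shared by the deletion and tagging constructs. For a CDS it is the
#' reverse complement of (stop codon + N-3 downstream bases); for
#' non-coding features the reverse complement of the N bases downstream of
#' the end coordinate. Width is exactly N.
#'
#' @inheritParams design_deletion_forward
#' @return Untailed homology arm of width \code{N}.
#' @export
design_reverse <- function(feature, genome, params) {
  n <- params$homology_length
  if (params$ftype == "CDS") {
    g <- .genome_chars(genome)
    f <- .feature_fields(feature)
    chrom_seq <- .chrom_seq_of(g, f$chrom)
    feat_len <- f$end - f$start + 1L
    revcomp(.sense_window(chrom_seq, f$start, f$end, f$strand,
                          feat_len - 2L, feat_len + n - 3L))
  } else {
    revcomp(sense_flank(genome, feature, "downstream", n))
  }
}

#' Append a constant priming-site tail to a homology arm
#'
#' The tail goes at the 3' end of the long primer: genomic homology 5',
#' vector priming site 3'.
#'
#' @param homology Untailed homology arm (non-empty).
#' @param mode \code{"fwd_standard"} (MCS forward site), \code{"fwd_utr"}
#'   (adh1-terminator site, for 3'UTR deletion) or \code{"rev"}.
#' @param tails A \code{\link{pfa6a_tails}} set.
#' @return The tailed long primer.
#' @export
attach_tail <- function(homology, mode = c("fwd_standard", "fwd_utr", "rev"),
                        tails = pfa6a_tails()) {
  mode <- match.arg(mode)
  if (any(!nzchar(homology))) stop("homology arm must be non-empty", call. = FALSE)
  tail <- switch(mode, fwd_standard = tails$fwd_tail, fwd_utr = tails$utr_fwd_tail,
                 rev = tails$rev_tail)
  paste0(homology, tail)
}

#' Design all primers for one feature
#'
#' @param feature One catalog row.
#' @param genome Genome.
#' @param params \code{\link{design_params}}.
#' @param tails Tail set.
#' @return One-row data.frame with the untailed and tailed forward deletion,
#'   forward tagging (CDS only; empty string otherwise) and reverse
#'   primers, plus the feature's identifying columns.
#' @export
design_primer_set <- function(feature, genome, params, tails = pfa6a_tails()) {
  fwd_del <- design_deletion_forward(feature, genome, params)
  fwd_mode <- if (params$ftype == "3UTR") "fwd_utr" else "fwd_standard"
  rev <- design_reverse(feature, genome, params)
  is_cds <- params$ftype == "CDS"
  fwd_tag <- if (is_cds) design_ctag_forward(feature, genome, params) else ""
  data.frame(
    systematic_name = feature$systematic_name,
    common_name = feature$common_name,
    chrom_id = feature$chrom_id,
    start = feature$start,
    end = feature$end,
    strand = feature$strand,
    fwd_del = fwd_del,
    fwd_del_tailed = attach_tail(fwd_del, fwd_mode, tails),
    fwd_tag = fwd_tag,
    fwd_tag_tailed = if (is_cds) attach_tail(fwd_tag, "fwd_standard", tails) else "",
    rev = rev,
    rev_tailed = attach_tail(rev, "rev", tails),
    stringsAsFactors = FALSE
  )
}

#' Design primers for a whole catalog
#'
#' Batch driver: one primer row per catalogued feature, in catalog order,
#' with the overlap columns filled from \code{universe} when provided (the
#' universe should be the union of the genome's CDS and ncRNA catalogs; see
#' \code{\link{annotate_overlaps}}).
#'
#' @param catalog A \code{\link{build_catalog}} result.
#' @param genome Genome.
#' @param params \code{\link{design_params}}.
#' @param tails Tail set.
#' @param universe Optional catalog of CDS+ncRNA features for
#'   neighbour-disruption reporting.
#' @return A primer-table data.frame (see \code{\link{write_primer_table}}
#'   for the column contract).
#' @export
design_primers <- function(catalog, genome, params, tails = pfa6a_tails(),
                           universe = NULL) {
  g <- .genome_chars(genome)
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    design_primer_set(catalog[i, , drop = FALSE], g, params, tails)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    design_primer_set_empty()
  if (!is.null(universe) && nrow(out) > 0L) {
    ov <- annotate_overlaps(catalog, universe)
    stopifnot(identical(ov$systematic_name, out$systematic_name))
    out$overlap_names <- ov$overlap_names
    out$overlap_count <- ov$overlap_count
  } else {
    out$overlap_names <- character(nrow(out))
    out$overlap_count <- integer(nrow(out))
  }
  rownames(out) <- NULL
  out
}

# Zero-row primer table with the full column schema.
design_primer_set_empty <- function() {
  data.frame(systematic_name = character(0L), common_name = character(0L),
             chrom_id = character(0L), start = integer(0L), end = integer(0L),
             strand = character(0L), fwd_del = character(0L),
             fwd_del_tailed = character(0L), fwd_tag = character(0L),
             fwd_tag_tailed = character(0L), rev = character(0L),
             rev_tailed = character(0L), stringsAsFactors = FALSE)
}
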