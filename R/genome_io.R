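# Reading and normalising genome FASTA and GFF3 annotation input.

#' Read a whole-genome FASTA file
#'
#' Reads a (possibly line-wrapped, multi-record) FASTA file into a
#' \link[Biostrings]{DNAStringSet}. Record names are normalised to the first
#' whitespace-delimited token of each header, because public yeast genome
#' headers frequently embed free text after the chromosome name. Lowercase
#' bases are uppercased. Bases outside \code{A,C,G,T,N} (IUPAC ambiguity
#' codes, common in resequenced strains) are kept verbatim but counted and
#' reported once per chromosome via a warning, so that downstream design
#' never silently alters the input sequence.
#'
#' @param path Path to a FASTA file.
#' @return A \code{DNAStringSet}, one element per record in file order;
#'   element names are chromosome ids, \code{width()} gives lengths.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 some description", "ACGT", "acgt"), fa)
#' g <- read_genome_fasta(fa)
#' names(g)          # "chr1"
#' as.character(g)   # "ACGTACGT"
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  non_blank <- head_lines[nzchar(trimws(head_lines))]
  if (length(non_blank) == 0L) {
    stop("FASTA parse error: file is empty: ", path, call. = FALSE)
  }
  if (!startsWith(non_blank[[1L]], ">")) {
    stop("FASTA parse error: first non-blank line is not a '>' header: ",
         path, call. = FALSE)
  }
  genome <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(genome) == 0L) {
    stop("FASTA parse error: no records in ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(genome), "[ \t]+"), `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("FASTA parse error: duplicate chromosome id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(genome) <- ids
  freq <- Biostrings::alphabetFrequency(genome)
  plain <- c("A", "C", "G", "T", "N")
  other <- rowSums(freq[, !colnames(freq) %in% plain, drop = FALSE])
  for (i in which(other > 0L)) {
    warning(sprintf("chromosome %s: %d base(s) outside {A,C,G,T,N} kept verbatim",
                    ids[[i]], other[[i]]), call. = FALSE)
  }
  genome
}

#' Write a genome back to FASTA
#'
#' Round-trip companion to \code{\link{read_genome_fasta}}: re-reading the
#' written file yields identical ids, sequences and lengths.
#'
#' @param genome A \code{DNAStringSet} (or named character vector of
#'   sequences).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, filepath = path, format = "fasta")
  invisible(path)
}

# Parse one GFF3 attribute column ("k1=v1;k2=v2") into a named character
# vector. Percent-escapes are decoded per the GFF3 spec.
parse_gff3_attributes <- function(text) {
  if (is.na(text) || !nzchar(text) || identical(text, ".")) {
    return(stats::setNames(character(0L), character(0L)))
  }
  parts <- strsplit(text, ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(trimws(parts))]
  keys <- character(length(parts))
  vals <- character(length(parts))
  for (i in seq_along(parts)) {
    kv <- strsplit(parts[[i]], "=", fixed = TRUE)[[1L]]
    keys[[i]] <- trimws(kv[[1L]])
    v <- if (length(kv) >= 2L) paste(kv[-1L], collapse = "=") else ""
    vals[[i]] <- utils::URLdecode(v)
  }
  stats::setNames(vals, keys)
}

.attr_or_na <- function(attrs, key) {
  if (key %in% names(attrs) && nzchar(attrs[[key]])) attrs[[key]] else NA_character_
}

#' Read a GFF3 annotation file into a feature-line table
#'
#' Parses the tab-delimited nine-column GFF3 body into one row per feature
#' line. Lines starting with \code{#} are skipped; parsing stops at a
#' \code{##FASTA} directive. The attribute column is split on \code{;} then
#' \code{=}, and the \code{ID}, \code{Parent} and \code{Name} attributes are
#' lifted into their own columns (the raw attribute string is retained).
#' Coordinates are 1-based inclusive and are kept in that convention
#' throughout the package. Strand is normalised to ASCII \code{+}/\code{-}
#' (a Unicode minus sign is accepted); \code{.} and \code{?} strands are kept
#' here and rejected later, when a feature of that strand is actually
#' requested for design.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns \code{seqid, source, ftype, start, end,
#'   score, strand, phase, attributes, ID, Parent, Name, line} (\code{line}
#'   is the 1-based line number in the file, for diagnostics).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) {
    stop("GFF3 file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  fasta_at <- which(startsWith(lines, "##FASTA"))
  if (length(fasta_at) > 0L) {
    lines <- lines[seq_len(fasta_at[[1L]] - 1L)]
  }
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  cols <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_col <- lengths(cols)
  if (any(n_col < 8L)) {
    bad <- keep[which(n_col < 8L)[1L]]
    stop(sprintf("GFF3 parse error at line %d: expected >= 8 tab-delimited columns, got %d",
                 bad, n_col[which(n_col < 8L)[1L]]), call. = FALSE)
  }
  col <- function(i) vapply(cols, function(x) if (length(x) >= i) x[[i]] else "",
                            character(1L))
  start_txt <- col(4L)
  end_txt <- col(5L)
  start <- suppressWarnings(as.integer(start_txt))
  end <- suppressWarnings(as.integer(end_txt))
  bad_coord <- which(is.na(start) | is.na(end) |
                       start_txt != as.character(start) |
                       end_txt != as.character(end))
  if (length(bad_coord) > 0L) {
    stop(sprintf("GFF3 parse error at line %d: non-integer coordinates '%s'..'%s'",
                 keep[bad_coord[[1L]]], start_txt[bad_coord[[1L]]],
                 end_txt[bad_coord[[1L]]]), call. = FALSE)
  }
  bad_span <- which(start < 1L | end < start)
  if (length(bad_span) > 0L) {
    stop(sprintf("GFF3 parse error at line %d: invalid span %d..%d (need 1 <= start <= end)",
                 keep[bad_span[[1L]]], start[bad_span[[1L]]], end[bad_span[[1L]]]),
         call. = FALSE)
  }
  strand <- col(7L)
  strand[strand == "−"] <- "-"
  attr_txt <- col(9L)
  attrs <- lapply(attr_txt, parse_gff3_attributes)
  out <- data.frame(
    seqid = col(1L),
    source = col(2L),
    ftype = col(3L),
    start = start,
    end = end,
    score = col(6L),
    strand = strand,
    phase = col(8L),
    attributes = attr_txt,
    ID = vapply(attrs, .attr_or_na, character(1L), key = "ID"),
    Parent = vapply(attrs, .attr_or_na, character(1L), key = "Parent"),
    Name = vapply(attrs, .attr_or_na, character(1L), key = "Name"),
    line = keep,
    stringsAsFactors = FALSE
  )
  out
}

#' Check that an annotation and a genome belong together
#'
#' Every \code{seqid} used by the annotation must name a chromosome present
#' in the genome; otherwise primer design would be undefined. Called before
#' any design begins.
#'
#' @param records Annotation table from \code{\link{read_gff3}}.
#' @param genome Genome from \code{\link{read_genome_fasta}}.
#' @return \code{TRUE}, invisibly; raises an error on mismatch.
#' @export
validate_annotation_genome <- function(records, genome) {
  missing <- setdiff(unique(records$seqid), names(genome))
  if (length(missing) > 0L) {
    stop("annotation references chromosome(s) absent from the genome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
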