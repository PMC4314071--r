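# Turning raw annotation lines into one catalogued target per feature.

# Feature codes understood by the design pipeline, with the GFF3 "type"
# string each one matches by default. 3'UTR features are typed
# "three_prime_UTR" in standard GFF3.
.feature_codes <- c(CDS = "CDS", ncRNA = "ncRNA", `3UTR` = "three_prime_UTR",
                    tRNA = "tRNA")

#' Normalise a feature-type code
#'
#' Accepts the canonical codes \code{"CDS"}, \code{"ncRNA"}, \code{"3UTR"},
#' \code{"tRNA"} in any case (and \code{"3'UTR"}/\code{"cds"}-style
#' variants), returning the canonical spelling.
#'
#' @param ftype Feature-type code.
#' @return One of \code{"CDS"}, \code{"ncRNA"}, \code{"3UTR"}, \code{"tRNA"}.
#' @export
normalize_ftype <- function(ftype) {
  key <- toupper(gsub("'", "", as.character(ftype)[[1L]]))
  key <- switch(key,
                "CDS" = "CDS",
                "NCRNA" = "ncRNA",
                "3UTR" = "3UTR",
                "THREE_PRIME_UTR" = "3UTR",
                "TRNA" = "tRNA",
                stop("unknown feature type: ", ftype,
                     " (expected CDS, ncRNA, 3UTR or tRNA)", call. = FALSE))
  key
}

# Group key for one annotation line: Parent when present, else ID.
.group_key <- function(records) {
  key <- records$Parent
  key[is.na(key)] <- records$ID[is.na(key)]
  key
}

# Collapse transcript-level group keys onto genes: when two or more keys
# share the same base after stripping one trailing ".<digits>" segment
# (e.g. g7.1 and g7.2), only the lexicographically first transcript is kept
# and the shared base becomes the systematic name.
.collapse_transcripts <- function(keys) {
  base <- sub("\\.[0-9]+$", "", keys)
  out <- data.frame(key = keys, name = keys, keep = TRUE,
                    stringsAsFactors = FALSE)
  for (b in unique(base[duplicated(base)])) {
    sib <- which(base == b & keys != b)
    if (length(sib) >= 2L) {
      ordered <- sib[order(keys[sib])]
      out$keep[ordered[-1L]] <- FALSE
      out$name[ordered[[1L]]] <- b
      message(sprintf("gene %s: %d transcripts found; using %s",
                      b, length(sib), keys[ordered[[1L]]]))
    }
  }
  out
}

#' Build a catalog of design targets from annotation records
#'
#' Selects annotation lines whose GFF3 type matches the requested feature
#' code (or one of the caller-supplied aliases, e.g. pseudogene and
#' transposable-element types treated as genes when cataloguing CDSs),
#' groups them by parent identity, and emits one target per group spanning
#' \code{min(start)..max(end)} — so a multi-exon CDS contributes a single
#' feature covering its genomic envelope. When a gene carries several
#' transcripts the lexicographically first transcript is used and the rest
#' are dropped with a note. Features whose strand is \code{.} or \code{?}
#' are skipped with a warning (primer geometry is undefined without
#' orientation), as are groups mixing strands or chromosomes.
#'
#' @param records Annotation table from \code{\link{read_gff3}}.
#' @param ftype Feature code: \code{"CDS"}, \code{"ncRNA"}, \code{"3UTR"} or
#'   \code{"tRNA"}.
#' @param type_aliases Optional character vector of additional GFF3 type
#'   strings to match (e.g. \code{c("pseudogene", "transposable_element_gene")}).
#' @return A data.frame of class \code{feature_catalog} with columns
#'   \code{systematic_name, common_name, chrom_id, start, end, strand,
#'   ftype}, sorted by (chromosome, start, systematic name). Coordinates are
#'   1-based inclusive, exactly as annotated.
#' @export
build_catalog <- function(records, ftype, type_aliases = character(0L)) {
  code <- normalize_ftype(ftype)
  wanted <- c(.feature_codes[[code]], type_aliases)
  hits <- records[records$ftype %in% wanted, , drop = FALSE]
  empty <- data.frame(systematic_name = character(0L),
                      common_name = character(0L),
                      chrom_id = character(0L),
                      start = integer(0L), end = integer(0L),
                      strand = character(0L), ftype = character(0L),
                      stringsAsFactors = FALSE)
  class(empty) <- c("feature_catalog", "data.frame")
  if (nrow(hits) == 0L) {
    return(empty)
  }
  key <- .group_key(hits)
  no_key <- is.na(key)
  if (any(no_key)) {
    warning(sprintf("%d matching line(s) without ID or Parent attribute skipped",
                    sum(no_key)), call. = FALSE)
    hits <- hits[!no_key, , drop = FALSE]
    key <- key[!no_key]
  }
  if (nrow(hits) == 0L) return(empty)
  keys <- sort(unique(key))
  plan <- .collapse_transcripts(keys)
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    if (!plan$keep[[i]]) next
    grp <- hits[key == plan$key[[i]], , drop = FALSE]
    strands <- unique(grp$strand)
    chroms <- unique(grp$seqid)
    if (length(chroms) > 1L || length(strands) > 1L) {
      warning(sprintf("feature %s skipped: segments mix %s", plan$name[[i]],
                      if (length(chroms) > 1L) "chromosomes" else "strands"),
              call. = FALSE)
      next
    }
    if (!strands %in% c("+", "-")) {
      warning(sprintf("feature %s skipped: strand '%s' gives no orientation for primer design",
                      plan$name[[i]], strands), call. = FALSE)
      next
    }
    nm <- grp$Name[!is.na(grp$Name)]
    rows[[i]] <- data.frame(
      systematic_name = plan$name[[i]],
      common_name = if (length(nm) > 0L) nm[[1L]] else "",
      chrom_id = chroms,
      start = min(grp$start),
      end = max(grp$end),
      strand = strands,
      ftype = code,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) return(empty)
  if (anyDuplicated(out$systematic_name)) {
    stop("duplicate systematic name(s) in catalog: ",
         paste(unique(out$systematic_name[duplicated(out$systematic_name)]),
               collapse = ", "), call. = FALSE)
  }
  out <- out[order(out$chrom_id, out$start, out$systematic_name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_catalog", "data.frame")
  out
}

#' Check the start/stop-codon conventions of a CDS feature
#'
#' A conventional CDS begins with \code{ATG} on its sense strand and ends in
#' one of \code{TAA}, \code{TAG}, \code{TGA}. Pseudogenes, truncated ORFs
#' and annotation quirks violate this; such features still get primers (the
#' geometry is defined regardless), so this check only produces notes, one
#' per violated convention, and never blocks design.
#'
#' @param feature One catalog row (one-row data.frame or list with
#'   \code{systematic_name, chrom_id, start, end, strand}).
#' @param genome Genome from \code{\link{read_genome_fasta}}.
#' @return A data.frame with columns \code{feature, kind, detail}; zero rows
#'   when both conventions hold. \code{kind} is one of
#'   \code{"no_ATG_start"}, \code{"no_stop_end"}, \code{"other"}.
#' @export
validate_feature <- function(feature, genome) {
  notes <- list()
  note <- function(kind, detail) {
    data.frame(feature = feature$systematic_name, kind = kind,
               detail = detail, stringsAsFactors = FALSE)
  }
  sense <- feature_sequence(genome, feature)
  len <- nchar(sense)
  if (len < 6L) {
    notes <- c(notes, list(note("other",
      sprintf("span of %d bp is too short for distinct start and stop codons", len))))
  }
  if (substr(sense, 1L, 3L) != "ATG") {
    notes <- c(notes, list(note("no_ATG_start",
      sprintf("sense sequence begins %s, not ATG", substr(sense, 1L, 3L)))))
  }
  if (!substr(sense, len - 2L, len) %in% c("TAA", "TAG", "TGA")) {
    notes <- c(notes, list(note("no_stop_end",
      sprintf("sense sequence ends %s, not a stop codon", substr(sense, len - 2L, len)))))
  }
  if (length(notes) == 0L) {
    return(data.frame(feature = character(0L), kind = character(0L),
                      detail = character(0L), stringsAsFactors = FALSE))
  }
  do.call(rbind, notes)
}
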