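# The three-file run output: header, primer database, check file. All
# tab-delimited UTF-8 text, importable into a spreadsheet unchanged.

.PRIMER_TABLE_COLUMNS <- c(
  "systematic_name", "common_name", "chromosome", "start", "end", "strand",
  "fwd_del", "fwd_del_tailed", "fwd_tag", "fwd_tag_tailed",
  "rev", "rev_tailed", "overlap_names", "overlap_count"
)

#' Build the manifest describing one run
#'
#' @param genome_label Human-readable label for the genome analysed.
#' @param ftype Feature code of the run.
#' @param homology_length Homology-arm length N used.
#' @param genome Genome (for chromosome names and lengths).
#' @param n_features Number of features designed (rows of the primer table).
#' @return A list of class \code{run_manifest}.
#' @export
run_manifest <- function(genome_label, ftype, homology_length, genome,
                         n_features) {
  g <- .genome_chars(genome)
  structure(list(genome_label = genome_label,
                 ftype = normalize_ftype(ftype),
                 homology_length = as.integer(homology_length),
                 chromosomes = data.frame(chrom_id = names(g),
                                          length = nchar(g),
                                          stringsAsFactors = FALSE,
                                          row.names = NULL),
                 n_features = as.integer(n_features)),
            class = "run_manifest")
}

#' Write the run header file
#'
#' File 1 of a run: genome label, feature type and homology length, one
#' line per chromosome with its length, the total feature count, and a
#' description of the columns of the primer table and check file. The
#' key/value lines are tab-separated so the file is both human-readable and
#' re-parseable.
#'
#' @param manifest A \code{\link{run_manifest}}.
#' @param path Output path.
#' @param n_rows Optional actual primer-table row count; when supplied it
#'   must equal \code{manifest$n_features} (internal consistency check).
#' @return \code{path}, invisibly.
#' @export
write_header_file <- function(manifest, path, n_rows = NULL) {
  if (!is.null(n_rows) && n_rows != manifest$n_features) {
    stop(sprintf("internal consistency error: manifest reports %d features but %d primer rows were produced",
                 manifest$n_features, n_rows), call. = FALSE)
  }
  lines <- c(
    paste0("genome\t", manifest$genome_label),
    paste0("feature_type\t", manifest$ftype),
    paste0("homology_length\t", manifest$homology_length),
    "chromosomes:",
    paste0(manifest$chromosomes$chrom_id, "\t", manifest$chromosomes$length),
    paste0("feature_count\t", manifest$n_features),
    "",
    "primer_table_columns:",
    paste(.PRIMER_TABLE_COLUMNS, collapse = "\t"),
    "check_file_columns:",
    "systematic_name\tfive_prime_region\tthree_prime_region\tfeature_sequence"
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write the primer database file
#'
#' File 2 of a run: one header row plus one row per feature, tab-delimited
#' with no quoting. Coordinates are echoed exactly as annotated (1-based
#' inclusive). On non-CDS runs the tagging columns are present but empty,
#' so the schema never shifts between feature types. Duplicate systematic
#' names are fatal before anything is written.
#'
#' @param primers Primer table from \code{\link{design_primers}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_primer_table <- function(primers, path) {
  if (anyDuplicated(primers$systematic_name)) {
    stop("duplicate systematic name(s) in primer table: ",
         paste(unique(primers$systematic_name[duplicated(primers$systematic_name)]),
               collapse = ", "), call. = FALSE)
  }
  out <- data.frame(systematic_name = primers$systematic_name,
                    common_name = primers$common_name,
                    chromosome = primers$chrom_id,
                    start = primers$start, end = primers$end,
                    strand = primers$strand,
                    fwd_del = primers$fwd_del,
                    fwd_del_tailed = primers$fwd_del_tailed,
                    fwd_tag = primers$fwd_tag,
                    fwd_tag_tailed = primers$fwd_tag_tailed,
                    rev = primers$rev, rev_tailed = primers$rev_tailed,
                    overlap_names = primers$overlap_names,
                    overlap_count = primers$overlap_count,
                    stringsAsFactors = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' Re-read a primer database file
#'
#' Inverse of \code{\link{write_primer_table}}; reconstructs every field,
#' with empty cells as empty strings (not NA).
#'
#' @param path Path to a primer table written by this package.
#' @return Primer-table data.frame in the internal column naming.
#' @export
read_primer_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                           colClasses = "character", encoding = "UTF-8")
  if (!identical(names(raw), .PRIMER_TABLE_COLUMNS)) {
    stop("not a primer table written by this package: ", path, call. = FALSE)
  }
  data.frame(systematic_name = raw$systematic_name,
             common_name = raw$common_name,
             chrom_id = raw$chromosome,
             start = as.integer(raw$start), end = as.integer(raw$end),
             strand = raw$strand,
             fwd_del = raw$fwd_del, fwd_del_tailed = raw$fwd_del_tailed,
             fwd_tag = raw$fwd_tag, fwd_tag_tailed = raw$fwd_tag_tailed,
             rev = raw$rev, rev_tailed = raw$rev_tailed,
             overlap_names = raw$overlap_names,
             overlap_count = as.integer(raw$overlap_count),
             stringsAsFactors = FALSE)
}

#' Write the check file
#'
#' File 3 of a run: per feature, its systematic name, the first and last
#' \code{end_region_len} sense bases, and the full sense sequence, for
#' manual verification against a genome browser. Features shorter than
#' \code{end_region_len} report their full sequence as both end regions.
#'
#' @param features A catalog or primer table (any data.frame carrying
#'   \code{systematic_name, chrom_id, start, end, strand}).
#' @param genome Genome.
#' @param path Output path.
#' @param end_region_len End-region width in bases (>= 1; default 30).
#' @return \code{path}, invisibly.
#' @export
write_check_file <- function(features, genome, path, end_region_len = 30L) {
  end_region_len <- as.integer(end_region_len)
  if (is.na(end_region_len) || end_region_len < 1L) {
    stop("end_region_len must be >= 1", call. = FALSE)
  }
  g <- .genome_chars(genome)
  n <- nrow(features)
  five <- character(n)
  three <- character(n)
  full <- character(n)
  for (i in seq_len(n)) {
    s <- feature_sequence(g, features[i, , drop = FALSE])
    len <- nchar(s)
    k <- min(end_region_len, len)
    five[[i]] <- substr(s, 1L, k)
    three[[i]] <- substr(s, len - k + 1L, len)
    full[[i]] <- s
  }
  out <- data.frame(systematic_name = features$systematic_name,
                    five_prime_region = five, three_prime_region = three,
                    feature_sequence = full, stringsAsFactors = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}
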