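# Neighbour-disruption reporting: which catalogued features does deleting a
# target physically remove part of?

#' Neighbours disrupted by deleting one target
#'
#' A neighbour is disrupted when its span intersects the deleted span on the
#' same chromosome, comparing closed 1-based intervals
#' (\code{other.start <= target.end} and \code{other.end >= target.start});
#' mere adjacency is not overlap. The comparison is strand-agnostic — an
#' antisense ncRNA is destroyed by the deletion regardless of strand — and
#' considers the feature span only, not the homology arms, because the
#' cassette replaces exactly the span while the arms are regenerated by
#' recombination. The target itself is never its own neighbour.
#'
#' @param target One catalog row.
#' @param universe Catalog of candidate neighbours; conventionally the union
#'   of the genome's CDS and ncRNA catalogs, both strands.
#' @return A list of class \code{overlap_report}: \code{feature} (the
#'   target's systematic name), \code{neighbors} (systematic names ordered
#'   by (start, name)) and \code{count}.
#' @export
find_disrupted_neighbors <- function(target, universe) {
  hit <- universe$chrom_id == target$chrom_id &
    universe$systematic_name != target$systematic_name &
    universe$start <= target$end &
    universe$end >= target$start
  nb <- universe[hit, , drop = FALSE]
  nb <- nb[order(nb$start, nb$systematic_name), , drop = FALSE]
  structure(list(feature = target$systematic_name,
                 neighbors = nb$systematic_name,
                 count = nrow(nb)),
            class = "overlap_report")
}

#' Disrupted-neighbour columns for a whole catalog
#'
#' Batch form of \code{\link{find_disrupted_neighbors}}, computed with
#' \code{\link[GenomicRanges]{findOverlaps}} so that whole-genome runs stay
#' fast. Neighbour names within a row are joined with \code{";"}.
#'
#' @param targets Catalog of deletion targets.
#' @param universe Catalog of candidate neighbours (CDS + ncRNA).
#' @return data.frame with \code{systematic_name, overlap_names,
#'   overlap_count}, one row per target in target order.
#' @export
annotate_overlaps <- function(targets, universe) {
  out <- data.frame(systematic_name = targets$systematic_name,
                    overlap_names = character(nrow(targets)),
                    overlap_count = integer(nrow(targets)),
                    stringsAsFactors = FALSE)
  if (nrow(targets) == 0L || nrow(universe) == 0L) return(out)
  tg <- GenomicRanges::GRanges(targets$chrom_id,
                               IRanges::IRanges(targets$start, targets$end))
  un <- GenomicRanges::GRanges(universe$chrom_id,
                               IRanges::IRanges(universe$start, universe$end))
  hits <- GenomicRanges::findOverlaps(tg, un, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  self <- targets$systematic_name[qh] == universe$systematic_name[sh]
  qh <- qh[!self]
  sh <- sh[!self]
  if (length(qh) > 0L) {
    ord <- order(qh, universe$start[sh], universe$systematic_name[sh])
    qh <- qh[ord]
    sh <- sh[ord]
    names_by_target <- split(universe$systematic_name[sh], qh)
    idx <- as.integer(names(names_by_target))
    out$overlap_names[idx] <- vapply(names_by_target, paste, character(1L),
                                     collapse = ";")
    out$overlap_count[idx] <- lengths(names_by_target)
  }
  out
}
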