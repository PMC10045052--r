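## Redundancy removal before cross-type matching: reads already assembled
## into a contig carry no extra information, and contig parts matched to the
## other sample's contigs must not be matched again to its reads.

#' Drop reads assembled into the sample's own contigs
#'
#' Returns the reads of `RA` that are not exact substrings of any contig in
#' `CA`.  The search uses a multi-pattern automaton over the constant-width
#' read set (one linear pass per contig); read length and coverage are
#' carried over unchanged.
#'
#' @param RA A [read_bag()].
#' @param CA A [contig_set()].
#' @return A [read_bag()] with the assembled reads removed.
#' @export
filter_assembled_reads <- function(RA, CA) {
  stopifnot(inherits(RA, "read_bag"), inherits(CA, "contig_set"))
  if (length(RA$reads) == 0 || length(CA$contigs) == 0) return(RA)
  # a read containing n can never be an exact substring (n mismatches all)
  pats <- unique(RA$reads)
  pats <- pats[!grepl("n", pats, fixed = TRUE)]
  if (length(pats) == 0) return(RA)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(toupper(pats)))
  hit <- logical(length(pats))
  for (ctg in CA$contigs) {
    subj <- Biostrings::DNAString(toupper(ctg))
    hit <- hit | (Biostrings::countPDict(pd, subj) > 0)
  }
  assembled <- pats[hit]
  keep <- !(RA$reads %in% assembled)
  bag <- read_bag(RA$reads[keep], l = RA$l, coverage = RA$c)
  bag
}

#' Unmatched contig substrings (residual contigs)
#'
#' For each contig of `CA`, the complementary segments of its matched
#' intervals: sorting the (disjoint) matched `alpha` intervals and cutting
#' the contig around them yields the substrings that found no counterpart
#' in the other sample's contigs.  Empty segments are dropped.
#'
#' @param CA A [contig_set()].
#' @param matches A match set over `CA` from [match_sets()].
#' @return Character vector of residual substrings (possibly empty), with
#'   names `"<contig>:<start>-<end>"` recording provenance.
#' @export
residual_contigs <- function(CA, matches) {
  stopifnot(inherits(CA, "contig_set"))
  out <- character()
  for (i in seq_along(CA$contigs)) {
    alpha <- CA$contigs[i]
    n <- nchar(alpha)
    mi <- matches[matches$alpha_id == i, , drop = FALSE]
    if (nrow(mi) > 0) {
      mi <- mi[order(mi$a_start), , drop = FALSE]
      if (any(mi$a_start[-1] < mi$a_end[-nrow(mi)]))
        stop(sprintf("overlapping matched intervals for contig %d", i))
      starts <- c(0L, mi$a_end)
      ends <- c(mi$a_start, n)
    } else {
      starts <- 0L
      ends <- n
    }
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
    if (length(starts)) {
      segs <- substring(alpha, starts + 1, ends)
      names(segs) <- sprintf("%d:%d-%d", i, starts, ends)
      out <- c(out, segs)
    }
  }
  out
}
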