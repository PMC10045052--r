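## Read-bag distances: margin-tolerant read-read distance, Monge-Elkan
## aggregation and its scaled symmetric version.

#' Read-read distance
#'
#' The margin-gap edit distance between two reads: because read start
#' positions are random, the first `t` leading or trailing gaps are free.
#' For a bag with read length `l` and coverage `c`, use
#' `t = margin_budget(l, c)`.
#'
#' @param a,b Reads (equal length in the constant-length model, not
#'   enforced here).
#' @param t Free margin gap budget.
#' @return Non-negative integer distance.
#' @export
dist_rr <- function(a, b, t) margin_gap_distance(a, b, t)

#' Monge-Elkan distance between two read bags
#'
#' `(1/|RA|) * sum over a in RA of min over b in RB of dist_rr(a, b)`.
#' Asymmetric; lies in `[0, l]`.  With `use_filter`, the inner minimum is
#' first restricted to the reads of `RB` attaining the minimal q-gram
#' distance to `a` (all ties kept), which are then resolved by exact
#' dynamic programming.
#'
#' @param RA,RB Non-empty [read_bag()]s.
#' @param use_filter Apply the q-gram candidate prefilter?
#' @param q Gram length for the filter (3 suits typical read lengths).
#' @param t Margin budget; defaults to `margin_budget(l, c)` of `RA`.
#' @return Non-negative real.
#' @export
monge_elkan <- function(RA, RB, use_filter = TRUE, q = 3L, t = NULL) {
  stopifnot(inherits(RA, "read_bag"), inherits(RB, "read_bag"))
  if (length(RA$reads) == 0 || length(RB$reads) == 0)
    stop("Monge-Elkan distance needs two non-empty read bags")
  if (is.null(t)) {
    if (is.na(RA$c)) stop("coverage unset; supply t explicitly")
    t <- margin_budget(RA$l, RA$c)
  }
  cpp_monge_elkan(RA$reads, RB$reads, as.integer(t), as.integer(q),
                  isTRUE(use_filter))
}

#' Scaled symmetric Monge-Elkan distance (MESSG)
#'
#' Averages the two Monge-Elkan directions and rescales from the per-read
#' range `[0, l]` to the genome-length scale: multiplied by
#' `max(|RA|, |RB|) / c`, so the result estimates an edit distance in
#' nucleotides (the genome length estimate being `|R| * l / c`).
#'
#' @inheritParams monge_elkan
#' @return Non-negative real, in edit-distance (nt) units.
#' @export
messg <- function(RA, RB, use_filter = TRUE, q = 3L) {
  stopifnot(inherits(RA, "read_bag"), inherits(RB, "read_bag"))
  if (RA$l != RB$l)
    stop(sprintf("read lengths differ between bags (%d vs %d)", RA$l, RB$l))
  if (is.na(RA$c) || is.na(RB$c)) stop("both bags need coverage set")
  me_ab <- monge_elkan(RA, RB, use_filter, q)
  me_ba <- monge_elkan(RB, RA, use_filter, q)
  # max(|R|) / c under shared coverage; the max of the two per-bag genome
  # length estimates |R|/c when coverages differ
  scale <- max(length(RA$reads) / RA$c, length(RB$reads) / RB$c)
  0.5 * (me_ab + me_ba) * scale
}
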