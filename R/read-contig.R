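## Read-to-contig and contig-residual-to-reads distances.

#' Read-contig distance
#'
#' Minimum over candidate windows of the contig of the margin-gap distance
#' between the read and the window.  Candidate windows have length within
#' `[l - t, l + t]` (`l` the read length) at every offset; when the contig
#' is shorter than `l - t` the whole contig is the only window.  Exact mode
#' enumerates all windows; fast mode first locates minimal sliding-window
#' q-gram distances and applies the exact margin-gap DP only around those
#' offsets.
#'
#' @param a Read.
#' @param beta Contig string (non-empty).
#' @param t Free margin gap budget.
#' @param exact Exhaustive window enumeration instead of the q-gram
#'   localization.
#' @param q Gram length used by the fast mode.
#' @return Non-negative integer distance; 0 whenever `a` occurs in `beta`.
#' @export
dist_rc <- function(a, beta, t, exact = FALSE, q = 3L) {
  stopifnot(nchar(beta) >= 1, t >= 0)
  cpp_dist_rc(as.character(a), as.character(beta), as.integer(t),
              as.integer(q), isTRUE(exact))
}

#' Contig-residual-to-reads distance
#'
#' A residual substring of length `|alpha_res|` should be covered by about
#' `k = floor(|alpha_res| * c / l)` reads.  The distance is the sum of the
#' `k` smallest read-to-residual distances over the (filtered) read bag;
#' `k = 0` contributes nothing.  When fewer than `k` reads are available,
#' each missing read is charged the maximal per-read cost `l`, so sparse
#' bags do not look spuriously close (configurable via `pad_missing`).
#'
#' @param alpha_res Residual contig substring.
#' @param RB A [read_bag()] carrying `l` and `c`.
#' @param t Margin budget; defaults to `margin_budget(l, c)` of `RB`.
#' @param exact,q Passed to [dist_rc()].
#' @param pad_missing Charge `l` per missing read when `|RB| < k`?
#' @return Non-negative integer.
#' @export
dist_cR <- function(alpha_res, RB, t = NULL, exact = FALSE, q = 3L,
                    pad_missing = TRUE) {
  stopifnot(inherits(RB, "read_bag"))
  if (is.na(RB$c)) stop("read bag needs coverage set")
  if (is.null(t)) t <- margin_budget(RB$l, RB$c)
  k <- floor(nchar(alpha_res) * RB$c / RB$l)
  if (k == 0) return(0L)
  as.integer(cpp_dist_cR(RB$reads, as.character(alpha_res), as.integer(t),
                         as.integer(q), isTRUE(exact), as.integer(k),
                         RB$l, isTRUE(pad_missing)))
}
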