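## Exact, banded and margin-tolerant edit distances.

#' Levenshtein distance
#'
#' Minimum number of insertions, deletions and substitutions transforming
#' `x` into `y`, by banded dynamic programming with iterative band doubling
#' (always exact).
#'
#' @param x,y Strings.
#' @return Non-negative integer distance.
#' @export
levenshtein <- function(x, y) {
  cpp_levenshtein(as.character(x), as.character(y))
}

#' Banded Levenshtein distance with a cutoff
#'
#' Returns the exact distance whenever it does not exceed `bound`, and `NA`
#' (the EXCEEDS marker) otherwise; the band follows Ukkonen's cutoff
#' heuristic.
#'
#' @param x,y Strings.
#' @param bound Non-negative cutoff.
#' @return Integer distance or `NA` if the distance exceeds `bound`.
#' @export
levenshtein_banded <- function(x, y, bound) {
  stopifnot(bound >= 0)
  r <- cpp_levenshtein_banded(as.character(x), as.character(y),
                              as.integer(bound))
  if (r < 0) NA_integer_ else r
}

#' Margin-gap edit distance
#'
#' Unit-cost edit distance in which, on each margin, the first `t` leading or
#' trailing gap symbols are free (whichever string the margin gaps fall on);
#' all internal gaps cost 1.  This compensates for the random placement of
#' fixed-length reads: two error-free reads sampled at most `t` positions
#' apart have distance 0.  With `t = 0` this is exactly [levenshtein()].
#'
#' @param x,y Strings.
#' @param t Non-negative free margin gap budget (nt).
#' @return Non-negative integer distance.
#' @export
margin_gap_distance <- function(x, y, t) {
  stopifnot(t >= 0)
  cpp_margin_gap(as.character(x), as.character(y), as.integer(t))
}

#' Post-normalized Levenshtein distance
#'
#' The ratio of the Levenshtein distance to the length of the longer string;
#' lies in `[0, 1]`.
#'
#' @param x,y Strings, not both empty.
#' @return Real number in `[0, 1]`.
#' @export
post_normalized <- function(x, y) {
  x <- as.character(x); y <- as.character(y)
  m <- max(nchar(x), nchar(y))
  if (m == 0) stop("post-normalized distance is undefined for two empty strings")
  levenshtein(x, y) / m
}

#' Free margin gap budget for a read bag
#'
#' The number of unpenalized leading/trailing gaps used when aligning reads:
#' `t = floor((l/c - 1) / 2)`, clamped at zero when coverage exceeds the read
#' length.  It equals half the expected start-position offset between two
#' reads covering the same locus.
#'
#' @param l Read length (nt).
#' @param c Fold coverage.
#' @return Non-negative integer budget.
#' @export
margin_budget <- function(l, c) {
  stopifnot(l >= 1, c > 0)
  max(0L, as.integer(floor((l / c - 1) / 2)))
}
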