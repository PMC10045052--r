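## q-gram profiles and distances: the acceleration layer.  The q-gram
## distance lower-bounds the Levenshtein distance via
## dist(A, B) >= dist_q(A, B) / (2q), which makes it a safe prefilter.

#' q-gram profile of a string
#'
#' Counts every length-`q` substring of `s`.  Profiles are sparse (only
#' observed grams are stored), so large `q` stays cheap.
#'
#' @param s String.
#' @param q Gram length, at least 1.
#' @return Object of class `qgram_profile` with fields `q`, `counts` (named
#'   integer vector) and `source_length`.
#' @export
qgram_profile <- function(s, q) {
  q <- as.integer(q)
  if (q < 1) stop("q must be at least 1")
  p <- cpp_qgram_profile(as.character(s), q)
  structure(p, class = "qgram_profile")
}

#' @export
print.qgram_profile <- function(x, ...) {
  cat(sprintf("qgram_profile: q=%d, %d distinct grams, source length %d\n",
              x$q, length(x$counts), x$source_length))
  invisible(x)
}

#' q-gram distance
#'
#' Manhattan (L1) distance between two q-gram count profiles.  Accepts
#' either two [qgram_profile()] objects or two strings with `q` supplied.
#'
#' @param p1,p2 Profiles or strings.
#' @param q Gram length, required when strings are given.
#' @return Non-negative integer.
#' @export
qgram_distance <- function(p1, p2, q = NULL) {
  if (is.character(p1) && is.character(p2)) {
    if (is.null(q)) stop("q is required when comparing strings")
    return(cpp_qgram_dist(p1, p2, as.integer(q)))
  }
  stopifnot(inherits(p1, "qgram_profile"), inherits(p2, "qgram_profile"))
  if (p1$q != p2$q)
    stop(sprintf("profiles have different q (%d vs %d)", p1$q, p2$q))
  grams <- union(names(p1$counts), names(p2$counts))
  c1 <- c2 <- setNames(integer(length(grams)), grams)
  c1[names(p1$counts)] <- p1$counts
  c2[names(p2$counts)] <- p2$counts
  sum(abs(c1 - c2))
}

#' Sliding-window q-gram distances of a read against a contig
#'
#' For every offset `o` (0-based), the q-gram distance between the read and
#' the length-`|read|` window of the contig starting at `o`, computed
#' incrementally (each step updates one entering and one leaving gram) and
#' bit-identical to from-scratch recomputation.
#'
#' @param read,contig Strings with `|contig| >= |read| >= q`.
#' @param q Gram length.
#' @return Data frame with columns `offset` and `distance` (empty when the
#'   contig is shorter than the read).
#' @export
sliding_read_windows <- function(read, contig, q) {
  d <- cpp_sliding_read_windows(as.character(read), as.character(contig),
                                as.integer(q))
  data.frame(offset = seq_along(d) - 1L, distance = as.integer(d))
}

#' Equal-length overlap candidates of two contigs
#'
#' Enumerates all equal-length overlap configurations of `alpha` against
#' `beta` (one sliding along the other, containment included) of length at
#' least `min_len`.  Each configuration is scored by the q-gram distance of
#' the two overlap substrings, computed incrementally, for every admissible
#' `q` given by [choose_q()].
#'
#' @param alpha,beta Contig strings.
#' @param min_len Minimal overlap length.
#' @return Data frame with columns `a_start`, `b_start`, `len`, `q`, `dist`.
#' @export
sliding_overlaps <- function(alpha, beta, min_len) {
  stopifnot(min_len >= 1)
  cpp_sliding_overlaps(as.character(alpha), as.character(beta),
                       as.integer(min_len))
}

#' Admissible q values for an overlap length
#'
#' The q-gram distance discriminates best for sequences of length about
#' `4^q`, so for overlap length `L` all `q >= 2` with
#' `4^(q-1) <= L < 4^(q+1)` are admissible (half-open, matching the
#' package-wide interval convention).  Lengths below 4 fall back to `q = 2`.
#'
#' @param overlap_length Positive integer.
#' @return Integer vector of admissible q values.
#' @export
choose_q <- function(overlap_length) {
  stopifnot(overlap_length >= 1)
  if (overlap_length < 4) return(2L)
  qmax <- floor(log(overlap_length, 4)) + 1
  qs <- 2:max(2, qmax)
  qs[4^(qs - 1) <= overlap_length & overlap_length < 4^(qs + 1)]
}

#' Cross-q comparable overlap score
#'
#' `distance / (q * overlap_length)`: dividing the per-position q-gram
#' distance by `q` makes scores comparable across different `q`, following
#' the `dist >= dist_q / (2q)` lower bound.
#'
#' @param distance q-gram distance of the overlap substrings.
#' @param overlap_length Overlap length, at least 1.
#' @param q Gram length, at least 1.
#' @return Non-negative real score.
#' @export
normalized_qgram_score <- function(distance, overlap_length, q) {
  stopifnot(overlap_length >= 1, q >= 1)
  distance / (q * overlap_length)
}
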