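## Combination of the four matching facets into the final genome distance
## and the all-pairs distance matrix.
##
## The directional pre-distance mixes the contig-contig measure dist_C with
## the read-level pre-measure dist_TT\R by the fraction w of the genome
## covered by matched contig sequence; the final distance symmetrizes the
## two directions and rescales from [0, 1] to edit-distance units by the
## genome length estimate l * |R| / c.

#' Distance from a read to the closest read or contig
#'
#' `min( min over b in RB of dist_rr(a, b), min over beta in CB of
#' dist_rc(a, beta) )`; a missing branch (no reads, or no contigs)
#' contributes infinity.  The read bag here is typically the
#' redundancy-filtered bag of the target sample.
#'
#' @param a Read.
#' @param RB Character vector of target reads (may be empty).
#' @param CB Character vector of target contigs (may be empty).
#' @param t Margin budget.
#' @param exact Use exhaustive read-contig windows.
#' @param q Gram length for the q-gram prefilters.
#' @return Non-negative integer.
#' @export
dist_rT <- function(a, RB, CB, t, exact = FALSE, q = 3L) {
  if (length(RB) == 0 && length(CB) == 0)
    stop("target sample has neither reads nor contigs")
  cpp_sum_dist_rT(as.character(a), as.character(RB), as.character(CB),
                  as.integer(t), as.integer(q), isTRUE(exact))
}

#' Read-level pre-measure between two samples
#'
#' Sums, over the filtered reads of the source sample, the distance to the
#' closest read or contig of the target, plus the residual-contig-to-reads
#' distances, and normalizes by `l * (|RA'| + sum of floor(|alpha'| c / l))`
#' (the value every term would take if maximally distant), giving a value
#' in `[0, 1]`.  An empty numerator side (nothing left to compare) yields 0.
#'
#' @param RA_f Filtered source reads (character vector).
#' @param CA_res Residual source contig substrings (character vector).
#' @param RB_f Filtered target reads (character vector).
#' @param CB Target contigs (character vector).
#' @param l Source read length.
#' @param c Source coverage.
#' @param exact,q Matching mode controls.
#' @param pad_missing See [dist_cR()].
#' @return Real in `[0, 1]`.
#' @export
dist_TT_minus_R <- function(RA_f, CA_res, RB_f, CB, l, c, exact = FALSE,
                            q = 3L, pad_missing = TRUE) {
  t <- margin_budget(l, c)
  quotas <- floor(nchar(CA_res) * c / l)
  den <- l * (length(RA_f) + sum(quotas))
  if (den == 0) return(0)
  num <- 0
  if (length(RA_f) > 0) {
    if (length(RB_f) == 0 && length(CB) == 0)
      stop("target sample has neither reads nor contigs")
    num <- num + cpp_sum_dist_rT(RA_f, as.character(RB_f),
                                 as.character(CB), as.integer(t),
                                 as.integer(q), isTRUE(exact))
  }
  # residual quotas and margins use the source sample's l and c
  for (ar in CA_res) {
    k <- floor(nchar(ar) * c / l)
    if (k == 0) next
    num <- num + cpp_dist_cR(as.character(RB_f), as.character(ar),
                             as.integer(t), as.integer(q), isTRUE(exact),
                             as.integer(k), as.integer(l),
                             isTRUE(pad_missing))
  }
  num / den
}

#' Weight of the contig-contig measure
#'
#' The fraction of the source genome covered by matched contig sequence:
#' `w = min(1, |match| * c / (|RA| * l))`, where `|match|` is the total
#' matched `alpha` length and `|RA| * l / c` estimates the genome length.
#' The clamp at 1 guards against over-assembly.
#'
#' @param matches Match set from [match_sets()].
#' @param n_reads Number of reads in the source bag (unfiltered).
#' @param l Read length.
#' @param c Coverage.
#' @return Real in `[0, 1]`.
#' @export
contig_weight <- function(matches, n_reads, l, c) {
  stopifnot(n_reads > 0)
  min(1, matched_length(matches) * c / (n_reads * l))
}

#' Directional pre-distance between two samples
#'
#' Runs the full directional pipeline: contig matching, redundancy
#' filtering, the read-level pre-measure, and the convex combination
#' `w * dist_C + (1 - w) * dist_TT\R`.
#'
#' @param TA,TB [sample_tuple()]s; `TA` is the source of the direction.
#' @param mode `"fast"` or `"exact"` matching.
#' @param min_overlap Contig match length threshold.
#' @param q Gram length for the read-level prefilters.
#' @param RA_f,RB_f Optional precomputed filtered read vectors.
#' @param matches Optional precomputed [match_sets()] result for the
#'   direction `TA` to `TB`.
#' @return List with `dist_C`, `dist_TT_minus_R`, `w`, `dist_TT`,
#'   `matched_length` (a directional breakdown).
#' @export
dist_TT <- function(TA, TB, mode = c("fast", "exact"), min_overlap = 20L,
                    q = 3L, RA_f = NULL, RB_f = NULL, matches = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(TA, "sample_tuple"), inherits(TB, "sample_tuple"))
  exact <- mode == "exact"
  l <- TA$reads$l
  c_ <- TA$reads$c
  if (is.na(c_)) stop(sprintf("sample '%s' has no coverage set", TA$label))
  if (is.null(matches))
    matches <- match_sets(TA$contigs, TB$contigs, mode, min_overlap)
  dC <- dist_C(TA$contigs, TB$contigs, matches = matches)
  if (is.null(RA_f)) RA_f <- filter_assembled_reads(TA$reads, TA$contigs)$reads
  if (is.null(RB_f)) RB_f <- filter_assembled_reads(TB$reads, TB$contigs)$reads
  CA_res <- residual_contigs(TA$contigs, matches)
  dTTR <- dist_TT_minus_R(RA_f, CA_res, RB_f, TB$contigs$contigs, l, c_,
                          exact = exact, q = q)
  n_reads <- length(TA$reads$reads)
  w <- if (n_reads > 0) contig_weight(matches, n_reads, l, c_) else 1
  list(dist_C = dC, dist_TT_minus_R = dTTR, w = w,
       dist_TT = w * dC + (1 - w) * dTTR,
       matched_length = matched_length(matches))
}

#' Final genome distance between two samples
#'
#' Symmetrized pre-distance rescaled to edit-distance units:
#' `0.5 * (dist_TT(A,B) + dist_TT(B,A)) * l * max(|RA|, |RB|) / c`.  Each
#' direction computes its own matches and filtering.  Both samples must
#' have reads (the scale is undefined otherwise).
#'
#' @inheritParams dist_TT
#' @param breakdown Also return the per-direction diagnostics.
#' @param RA_f,RB_f Optional precomputed redundancy-filtered read vectors
#'   (computed from the samples when missing; [distance_matrix()] passes
#'   them to avoid refiltering per pair).
#' @return Non-negative real distance (nt), or a list when
#'   `breakdown = TRUE`.
#' @export
final_distance <- function(TA, TB, mode = c("fast", "exact"),
                           min_overlap = 20L, q = 3L, breakdown = FALSE,
                           RA_f = NULL, RB_f = NULL) {
  mode <- match.arg(mode)
  if (length(TA$reads$reads) == 0 || length(TB$reads$reads) == 0)
    stop("final distance needs reads on both samples (scale undefined)")
  if (is.na(TA$reads$c) || is.na(TB$reads$c))
    stop("both samples need coverage set")
  if (is.null(RA_f)) RA_f <- filter_assembled_reads(TA$reads, TA$contigs)$reads
  if (is.null(RB_f)) RB_f <- filter_assembled_reads(TB$reads, TB$contigs)$reads
  mm <- match_sets_both(TA$contigs, TB$contigs, mode, min_overlap)
  ab <- dist_TT(TA, TB, mode, min_overlap, q, RA_f = RA_f, RB_f = RB_f,
                matches = mm$ab)
  ba <- dist_TT(TB, TA, mode, min_overlap, q, RA_f = RB_f, RB_f = RA_f,
                matches = mm$ba)
  # l * max(|R|) / c under shared parameters; the max of the per-bag genome
  # length estimates l * |R| / c otherwise
  scale <- max(TA$reads$l * length(TA$reads$reads) / TA$reads$c,
               TB$reads$l * length(TB$reads$reads) / TB$reads$c)
  d <- 0.5 * (ab$dist_TT + ba$dist_TT) * scale
  if (!breakdown) return(d)
  list(distance = d, scale = scale, ab = ab, ba = ba)
}

#' All-pairs distance matrix
#'
#' Applies [final_distance()] to every unordered pair of samples.
#'
#' @param samples List of [sample_tuple()]s (at least 2, unique labels).
#' @inheritParams final_distance
#' @param verbose Print one line per pair.
#' @return Symmetric distance matrix with zero diagonal (see
#'   [dist_matrix()]).
#' @export
distance_matrix <- function(samples, mode = c("fast", "exact"),
                            min_overlap = 20L, q = 3L, verbose = FALSE) {
  mode <- match.arg(mode)
  n <- length(samples)
  if (n < 2) stop("need at least two samples")
  labels <- vapply(samples, function(s) s$label, character(1))
  if (anyDuplicated(labels)) stop("sample labels must be unique")
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  filtered <- lapply(samples, function(s)
    filter_assembled_reads(s$reads, s$contigs)$reads)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- final_distance(samples[[i]], samples[[j]], mode, min_overlap, q,
                          RA_f = filtered[[i]], RB_f = filtered[[j]])
      m[i, j] <- d
      m[j, i] <- d
      if (verbose)
        message(sprintf("%s - %s: %.1f", labels[i], labels[j], d))
    }
  }
  dist_matrix(m, labels)
}
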