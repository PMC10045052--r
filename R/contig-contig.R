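## Contig pair matching, weighted interval scheduling of the matches along
## each contig, and the contig-set distance.
##
## A match of contigs alpha and beta is the pair of substrings
## (alpha*, beta*) drawn from
##   suff(alpha) x pref(beta)  U  pref(alpha) x suff(beta)
##   U  sub(alpha) x {beta}    U  {alpha} x sub(beta)
## that minimizes the post-normalized Levenshtein distance
## edit / max(|alpha*|, |beta*|), subject to both lengths reaching
## min_overlap (default 20, to suppress small random overlaps).

schedule_by_alpha <- function(cands) {
  out <- empty_match_set()
  for (i in sort(unique(cands$alpha_id)))
    out <- rbind(out, schedule_matches(cands[cands$alpha_id == i, ,
                                             drop = FALSE]))
  rownames(out) <- NULL
  class(out) <- c("match_set", class(out))
  out
}

mirror_matches <- function(m) {
  data.frame(alpha_id = m$beta_id, beta_id = m$alpha_id,
             a_start = m$b_start, a_end = m$b_end,
             b_start = m$a_start, b_end = m$a_end,
             edit = m$edit, norm = m$norm)
}

match_pair_row <- function(alpha_id, beta_id, a_start, a_end, b_start,
                           b_end, edit) {
  la <- a_end - a_start
  lb <- b_end - b_start
  data.frame(alpha_id = alpha_id, beta_id = beta_id,
             a_start = a_start, a_end = a_end,
             b_start = b_start, b_end = b_end,
             edit = edit, norm = edit / max(la, lb))
}

empty_match_set <- function() {
  data.frame(alpha_id = integer(), beta_id = integer(),
             a_start = integer(), a_end = integer(),
             b_start = integer(), b_end = integer(),
             edit = integer(), norm = numeric())
}

#' Best match of two contigs (exhaustive)
#'
#' Enumerates the full candidate set of suffix-prefix overlaps and
#' substring containments and returns the candidate minimizing the
#' post-normalized Levenshtein distance.  Quadratic-to-cubic in the contig
#' lengths; intended for short contigs and for validating the fast matcher.
#'
#' @param alpha,beta Contig strings.
#' @param min_overlap Minimal length of both matched substrings.
#' @param alpha_id,beta_id Integer ids recorded in the result.
#' @return One-row data frame (`alpha_id`, `beta_id`, `a_start`, `a_end`,
#'   `b_start`, `b_end`, `edit`, `norm`; intervals 0-based half-open) or
#'   `NULL` when no candidate meets the length threshold.
#' @export
match_pair_exact <- function(alpha, beta, min_overlap = 20L,
                             alpha_id = 1L, beta_id = 1L) {
  stopifnot(min_overlap >= 1)
  r <- cpp_match_pair_exact(as.character(alpha), as.character(beta),
                            as.integer(min_overlap))
  if (length(r) == 0) return(NULL)
  match_pair_row(alpha_id, beta_id, r$a_start, r$a_end, r$b_start, r$b_end,
                 r$edit)
}

#' Best match of two contigs (fast, equal-length overlaps)
#'
#' Restricts the search to equal-length overlap configurations
#' (`|alpha*| = |beta*|`), scored in linear time by sliding q-gram
#' distances; the best-scoring configurations (within `slack` of the best
#' normalized score, at most `max_candidates`) are re-scored by the exact
#' banded Levenshtein distance.  Because q-gram count profiles saturate
#' between distant sequences, the candidate set additionally contains the
#' strongest exact shared-seed diagonals (`n_diag` peaks of
#' length-`seed_len` seed votes); the exact re-scoring arbitrates between
#' all candidates.  Searches a subset of the exhaustive candidate space, so
#' its normalized distance is never below the one found by
#' [match_pair_exact()].
#'
#' @inheritParams match_pair_exact
#' @param slack Relative tolerance around the best q-gram score within
#'   which candidates are re-scored exactly.
#' @param max_candidates Cap on exactly re-scored q-gram candidates.
#' @param seed_len Exact seed length for diagonal voting.
#' @param n_diag Number of diagonal-vote peaks added to the candidates.
#' @return As [match_pair_exact()].
#' @export
match_pair_fast <- function(alpha, beta, min_overlap = 20L,
                            alpha_id = 1L, beta_id = 1L,
                            slack = 0.05, max_candidates = 16L,
                            seed_len = 12L, n_diag = 3L) {
  stopifnot(min_overlap >= 1)
  alpha <- as.character(alpha); beta <- as.character(beta)
  ov <- cpp_sliding_overlaps(alpha, beta, as.integer(min_overlap))
  if (nrow(ov) > 0) {
    score <- ov$dist / (ov$q * ov$len)
    keep <- score <= min(score) + slack * max(min(score), 1e-12) + 1e-12
    ov <- ov[keep, , drop = FALSE]
    score <- score[keep]
    ord <- order(score, -ov$len, ov$a_start, ov$b_start)
    ov <- ov[ord, , drop = FALSE]
    dup <- duplicated(ov[, c("a_start", "b_start", "len")])
    ov <- ov[!dup, , drop = FALSE][seq_len(min(sum(!dup), max_candidates)), ,
                                   drop = FALSE]
  }
  cand <- data.frame(a_start = ov$a_start, b_start = ov$b_start,
                     len = ov$len,
                     lower = ceiling(ov$dist / (2 * ov$q)))
  # Exact shared-seed diagonal candidates: q-gram count profiles saturate on
  # distant sequences, where position-consistent exact seeds still mark the
  # homologous overlap; the exact re-scoring below arbitrates.
  dg <- cpp_diag_candidates(alpha, beta, as.integer(seed_len),
                            as.integer(min_overlap), as.integer(n_diag))
  if (nrow(dg) > 0)
    cand <- rbind(cand, data.frame(a_start = dg$a_start,
                                   b_start = dg$b_start, len = dg$len,
                                   lower = 0))
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[!duplicated(cand[, c("a_start", "b_start", "len")]), ,
               drop = FALSE]
  best <- NULL
  best_key <- NULL
  for (i in seq_len(nrow(cand))) {
    sa <- substr(alpha, cand$a_start[i] + 1, cand$a_start[i] + cand$len[i])
    sb <- substr(beta, cand$b_start[i] + 1, cand$b_start[i] + cand$len[i])
    # exact distance via band doubling seeded by the q-gram lower bound
    b <- max(1, cand$lower[i])
    repeat {
      ed <- cpp_levenshtein_banded(sa, sb, as.integer(b))
      if (ed >= 0) break
      b <- 2 * b
    }
    key <- c(ed / cand$len[i], -cand$len[i], cand$a_start[i], cand$b_start[i])
    if (is.null(best_key) || lex_less(key, best_key)) {
      best_key <- key
      best <- match_pair_row(alpha_id, beta_id,
                             cand$a_start[i], cand$a_start[i] + cand$len[i],
                             cand$b_start[i], cand$b_start[i] + cand$len[i],
                             ed)
    }
  }
  best
}

lex_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' Select non-conflicting matches along one contig
#'
#' Given candidate matches of one contig `alpha` against the contigs of the
#' other sample, selects the subset with pairwise-disjoint `alpha`
#' intervals maximizing the total weight
#' `max(|alpha*|, |beta*|) - 2 * edit` (identities minus errors), by the
#' standard weighted-interval-scheduling dynamic program.  Candidates whose
#' weight is not positive -- matches no better than aligning random DNA,
#' whose post-normalized distance sits at the random baseline of about 0.5
#' -- are discarded: leaving such a region unmatched hands it to the
#' residual-to-reads comparison, which is the more informative route.
#'
#' @param candidates Data frame of match rows sharing one `alpha_id`.
#' @return The selected subset of rows (possibly empty), ordered by
#'   `a_start`.
#' @export
schedule_matches <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0)
    return(empty_match_set())
  if (length(unique(candidates$alpha_id)) > 1)
    stop("schedule_matches expects candidates for a single contig")
  w <- pmax(candidates$a_end - candidates$a_start,
            candidates$b_end - candidates$b_start) - 2 * candidates$edit
  keep <- w > 0
  candidates <- candidates[keep, , drop = FALSE]
  if (nrow(candidates) == 0) return(empty_match_set())
  w <- w[keep]
  ord <- order(candidates$a_end, candidates$a_start)
  cand <- candidates[ord, , drop = FALSE]
  w <- w[ord]
  n <- nrow(cand)
  # p[i]: last candidate ending at or before cand$a_start[i] ([start,end)
  # intervals: touching is disjoint)
  p <- findInterval(cand$a_start, cand$a_end)
  opt <- numeric(n + 1)
  take <- logical(n)
  for (i in seq_len(n)) {
    with_i <- w[i] + opt[p[i] + 1]
    if (with_i > opt[i]) {  # strict: prefer fewer intervals on ties
      opt[i + 1] <- with_i
      take[i] <- TRUE
    } else {
      opt[i + 1] <- opt[i]
      take[i] <- FALSE
    }
  }
  sel <- logical(n)
  i <- n
  while (i >= 1) {
    if (take[i]) {
      sel[i] <- TRUE
      i <- p[i]
    } else i <- i - 1
  }
  out <- cand[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match two contig sets
#'
#' For each contig of `CA`, matches it against every contig of `CB`
#' ([match_pair_exact()] or [match_pair_fast()]), then resolves conflicts
#' along the contig with [schedule_matches()]; the union over contigs is
#' the admissible match set.
#'
#' @param CA,CB [contig_set()]s.
#' @param mode `"fast"` (default) or `"exact"`.
#' @param min_overlap Minimal matched substring length.
#' @return A match-set data frame (class `match_set`); per contig of `CA`
#'   the `alpha` intervals are pairwise disjoint.
#' @export
match_sets <- function(CA, CB, mode = c("fast", "exact"), min_overlap = 20L) {
  mode <- match.arg(mode)
  stopifnot(inherits(CA, "contig_set"), inherits(CB, "contig_set"))
  matcher <- if (mode == "fast") match_pair_fast else match_pair_exact
  cands <- empty_match_set()
  for (i in seq_along(CA$contigs)) {
    for (j in seq_along(CB$contigs)) {
      mp <- matcher(CA$contigs[i], CB$contigs[j], min_overlap,
                    alpha_id = i, beta_id = j)
      if (!is.null(mp)) cands <- rbind(cands, mp)
    }
  }
  schedule_by_alpha(cands)
}

# Both directions from one pass: the pair matcher is symmetric up to
# tie-breaking, so the reverse direction schedules the mirrored matches.
match_sets_both <- function(CA, CB, mode = c("fast", "exact"),
                            min_overlap = 20L) {
  mode <- match.arg(mode)
  matcher <- if (mode == "fast") match_pair_fast else match_pair_exact
  cands <- empty_match_set()
  for (i in seq_along(CA$contigs)) {
    for (j in seq_along(CB$contigs)) {
      mp <- matcher(CA$contigs[i], CB$contigs[j], min_overlap,
                    alpha_id = i, beta_id = j)
      if (!is.null(mp)) cands <- rbind(cands, mp)
    }
  }
  list(ab = schedule_by_alpha(cands), ba = schedule_by_alpha(mirror_matches(cands)))
}

#' Matched length of a match set
#'
#' Total length of the matched `alpha` substrings, the quantity weighting
#' the contig-contig measure in the combined distance.
#'
#' @param matches A match set from [match_sets()].
#' @return Non-negative integer.
#' @export
matched_length <- function(matches) {
  if (is.null(matches) || nrow(matches) == 0) return(0L)
  as.integer(sum(matches$a_end - matches$a_start))
}

#' Contig-set distance
#'
#' Sum of the edit distances over the admissible matches divided by the sum
#' of the longer matched lengths; in `[0, 1]`.  An empty match set (no
#' detectable shared sequence of at least `min_overlap` nt) yields the
#' maximal distance 1; its influence on the combined distance is then
#' anyway suppressed by a zero contig weight.
#'
#' @inheritParams match_sets
#' @param matches Optional precomputed [match_sets()] result.
#' @return Real in `[0, 1]`.
#' @export
dist_C <- function(CA, CB, mode = c("fast", "exact"), min_overlap = 20L,
                   matches = NULL) {
  if (is.null(matches)) matches <- match_sets(CA, CB, mode, min_overlap)
  if (nrow(matches) == 0) return(1)
  den <- sum(pmax(matches$a_end - matches$a_start,
                  matches$b_end - matches$b_start))
  sum(matches$edit) / den
}
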