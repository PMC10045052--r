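# Independent oracles and small-instance generators used across the suite.
# Every oracle here is deliberately implemented by a different route than
# the package (plain recursion, exhaustive enumeration, utils::adist) so
# agreement is evidence, not tautology.

DNA <- c("a", "c", "g", "t")

rnd_str <- function(n, alphabet = DNA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- Levenshtein by memoized brute-force recursion --------------------------

lev_oracle <- function(x, y) {
  xs <- strsplit(x, "")[[1]]
  ys <- strsplit(y, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > length(xs)) return(length(ys) - j + 1)
    if (j > length(ys)) return(length(xs) - i + 1)
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- as.integer(min(rec(i + 1, j) + 1L,
                        rec(i, j + 1) + 1L,
                        rec(i + 1, j + 1) + (xs[i] != ys[j])))
    memo[[key]] <- v
    v
  }
  as.integer(rec(1, 1))
}

# --- Margin-gap distance by exhaustive alignment enumeration ----------------
# Columns are "x" (gap in y), "y" (gap in x), "m" (match), "s" (substitution).
# The first t gap symbols of the maximal leading run lying in one string are
# free, likewise the trailing run; when the whole alignment is a single gap
# run both discounts apply to it without double counting.

score_columns <- function(cols, t) {
  n <- length(cols)
  if (n == 0) return(0)
  gaps <- cols %in% c("x", "y")
  subs <- sum(cols == "s")
  lead <- 0
  while (lead < n && cols[lead + 1] == cols[1] && gaps[lead + 1]) lead <- lead + 1
  if (!gaps[1]) lead <- 0
  trail <- 0
  while (trail < n && cols[n - trail] == cols[n] && gaps[n - trail]) trail <- trail + 1
  if (!gaps[n]) trail <- 0
  if (lead == n) {  # one single run
    free <- min(t, n) + min(t, n - min(t, n))
  } else {
    free <- min(t, lead) + min(t, trail)
  }
  sum(gaps) - free + subs
}

margin_oracle <- function(x, y, t) {
  xs <- strsplit(x, "")[[1]]
  ys <- strsplit(y, "")[[1]]
  best <- Inf
  rec <- function(i, j, cols) {
    if (i > length(xs) && j > length(ys)) {
      best <<- min(best, score_columns(cols, t))
      return(invisible(NULL))
    }
    if (i <= length(xs)) rec(i + 1, j, c(cols, "x"))
    if (j <= length(ys)) rec(i, j + 1, c(cols, "y"))
    if (i <= length(xs) && j <= length(ys))
      rec(i + 1, j + 1, c(cols, if (xs[i] == ys[j]) "m" else "s"))
  }
  rec(1, 1, character())
  best
}

# --- q-gram profile by direct substring extraction --------------------------

qgram_oracle <- function(s, q) {
  n <- nchar(s)
  if (n < q) return(integer())
  grams <- substring(s, 1:(n - q + 1), q:n)
  tab <- table(grams)
  setNames(as.integer(tab), names(tab))
}

qgram_dist_oracle <- function(a, b, q) {
  pa <- qgram_oracle(a, q)
  pb <- qgram_oracle(b, q)
  keys <- union(names(pa), names(pb))
  ca <- cb <- setNames(integer(length(keys)), keys)
  ca[names(pa)] <- pa
  cb[names(pb)] <- pb
  sum(abs(ca - cb))
}

# --- Exhaustive contig-contig match over S(alpha, beta) ---------------------
# Uses utils::adist (vectorized) as the edit-distance authority.

match_oracle <- function(alpha, beta, min_overlap) {
  na <- nchar(alpha); nb <- nchar(beta)
  best <- Inf
  upd <- function(ed, la, lb) {
    nr <- ed / pmax(la, lb)
    m <- suppressWarnings(min(nr))
    if (is.finite(m) && m < best) best <<- m
  }
  if (na >= min_overlap && nb >= min_overlap) {
    # suff(alpha) x pref(beta)
    sufs <- substring(alpha, 1:(na - min_overlap + 1), na)
    prefs <- substring(beta, 1, min_overlap:nb)
    ed <- adist(sufs, prefs)
    upd(ed, outer(nchar(sufs), rep(1, length(prefs))),
        outer(rep(1, length(sufs)), nchar(prefs)))
    # pref(alpha) x suff(beta)
    prefs_a <- substring(alpha, 1, min_overlap:na)
    sufs_b <- substring(beta, 1:(nb - min_overlap + 1), nb)
    ed <- adist(prefs_a, sufs_b)
    upd(ed, outer(nchar(prefs_a), rep(1, length(sufs_b))),
        outer(rep(1, length(prefs_a)), nchar(sufs_b)))
    # sub(alpha) x {beta}
    idx <- which(outer(1:na, 1:na, function(i, j) j - i + 1 >= min_overlap),
                 arr.ind = TRUE)
    subs_a <- substring(alpha, idx[, 1], idx[, 2])
    upd(as.vector(adist(subs_a, beta)), nchar(subs_a),
        rep(nb, length(subs_a)))
    # {alpha} x sub(beta)
    idx <- which(outer(1:nb, 1:nb, function(i, j) j - i + 1 >= min_overlap),
                 arr.ind = TRUE)
    subs_b <- substring(beta, idx[, 1], idx[, 2])
    upd(as.vector(adist(alpha, subs_b)), rep(na, length(subs_b)),
        nchar(subs_b))
  }
  if (is.finite(best)) best else NULL
}

# --- Weighted interval scheduling by subset enumeration ---------------------

wis_oracle <- function(starts, ends, weights) {
  n <- length(starts)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(sel) > 1) {
      o <- order(starts[sel])
      s <- starts[sel][o]; e <- ends[sel][o]
      if (any(s[-1] < e[-length(e)])) next
    }
    best <- max(best, sum(weights[sel]))
  }
  best
}

# --- Small simulated instances ---------------------------------------------

random_bag <- function(n, l, coverage = 2) {
  read_bag(replicate(n, rnd_str(l)), coverage = coverage)
}
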