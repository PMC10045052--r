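test_that("exhaustive contig match minimizes the post-normalized distance", {
  a <- rnd_str(30)
  mp <- match_pair_exact(a, a, 20)
  expect_equal(mp$edit, 0)
  expect_equal(c(mp$a_start, mp$a_end, mp$b_start, mp$b_end), c(0, 30, 0, 30))

  alpha <- rnd_str(60)
  beta <- substr(alpha, 16, 45)  # exact 30-nt substring
  mp <- match_pair_exact(alpha, beta, 20)
  expect_equal(mp$edit, 0)
  expect_equal(c(mp$a_start, mp$a_end), c(15, 45))
  expect_equal(c(mp$b_start, mp$b_end), c(0, 30))

  expect_null(match_pair_exact(rnd_str(10), rnd_str(10), 20))

  set.seed(51)
  for (i in 1:12) {
    x <- rnd_str(sample(8:40, 1)); y <- rnd_str(sample(8:40, 1))
    mp <- match_pair_exact(x, y, 5)
    expect_equal(mp$norm, match_oracle(x, y, 5), tolerance = 1e-12)
  }
})

test_that("fast matcher finds clean overlaps and never beats exact", {
  set.seed(52)
  ovl <- rnd_str(25)
  alpha <- paste0(rnd_str(50), ovl)
  beta <- paste0(ovl, rnd_str(50))
  mf <- match_pair_fast(alpha, beta, 20)
  me <- match_pair_exact(alpha, beta, 20)
  expect_equal(mf$edit, 0)
  expect_equal(me$edit, 0)
  expect_equal(c(mf$a_start, mf$a_end), c(50, 75))

  a <- rnd_str(40)
  expect_equal(match_pair_fast(a, a, 20)$norm, 0)

  for (i in 1:12) {
    x <- rnd_str(sample(25:100, 1)); y <- rnd_str(sample(25:100, 1))
    f <- match_pair_fast(x, y, 20)
    e <- match_pair_exact(x, y, 20)
    if (!is.null(f) && !is.null(e))
      expect_gte(f$norm, e$norm - 1e-12)
  }
})

test_that("interval scheduling maximizes total weight over disjoint matches", {
  row <- function(as, ae, bs, be, edit)
    pasdist:::match_pair_row(1L, 1L, as, ae, bs, be, edit)
  # weights max(len_a, len_b) - 2 edit: 5, 6, 5; optimum skips the middle
  cand <- rbind(row(0, 3, 0, 5, 0), row(2, 5, 10, 16, 0), row(3, 7, 20, 25, 0))
  sel <- schedule_matches(cand)
  expect_equal(sel$a_start, c(0, 3))
  expect_equal(sum(pmax(sel$a_end - sel$a_start,
                        sel$b_end - sel$b_start) - 2 * sel$edit), 10)

  disj <- rbind(row(0, 3, 0, 3, 1), row(5, 9, 0, 4, 0), row(12, 20, 0, 8, 2))
  expect_equal(nrow(schedule_matches(disj)), 3)
  expect_equal(nrow(schedule_matches(disj[0, ])), 0)

  set.seed(53)
  for (i in 1:40) {
    n <- sample(1:10, 1)
    starts <- sample(0:30, n, replace = TRUE)
    lens <- sample(1:10, n, replace = TRUE)
    edits <- sample(0:3, n, replace = TRUE)
    cand <- do.call(rbind, lapply(seq_len(n), function(k)
      row(starts[k], starts[k] + lens[k], 0, lens[k] + edits[k], edits[k])))
    sel <- schedule_matches(cand)
    w_sel <- sum(pmax(sel$a_end - sel$a_start,
                      sel$b_end - sel$b_start) - 2 * sel$edit)
    w_opt <- wis_oracle(starts, starts + lens,
                        pmax(0, pmax(lens, lens + edits) - 2 * edits))
    expect_equal(w_sel, w_opt)
    if (nrow(sel) > 1) {
      o <- order(sel$a_start)
      expect_true(all(sel$a_start[o][-1] >= sel$a_end[o][-nrow(sel)]))
    }
  }
})

test_that("contig-set matching keeps per-contig intervals disjoint", {
  set.seed(54)
  CA <- contig_set(replicate(3, rnd_str(sample(30:60, 1))))
  m_self <- match_sets(CA, CA, "exact")
  expect_equal(sum(m_self$edit), 0)
  expect_equal(dist_C(CA, CA, matches = m_self), 0)

  expect_equal(nrow(match_sets(CA, contig_set(), "fast")), 0)

  CB <- contig_set(replicate(4, rnd_str(sample(30:60, 1))))
  for (mode in c("exact", "fast")) {
    m <- match_sets(CA, CB, mode)
    for (a in unique(m$alpha_id)) {
      mi <- m[m$alpha_id == a, , drop = FALSE]
      o <- order(mi$a_start)
      if (nrow(mi) > 1)
        expect_true(all(mi$a_start[o][-1] >= mi$a_end[o][-nrow(mi)]))
    }
  }
})

test_that("the contig-set distance is normalized and maximal when unmatched", {
  g <- rnd_str(200)
  CA <- contig_set(c(substr(g, 1, 80), substr(g, 101, 180)))
  expect_equal(dist_C(CA, CA), 0)

  # no candidate can reach the length threshold: empty match set
  short <- contig_set(replicate(3, rnd_str(10)))
  expect_equal(dist_C(short, short, min_overlap = 20), 1)

  # a single 25-nt overlap with 2 edits: 2/25
  ovl <- rnd_str(25)
  ovl2 <- mutate_genome(ovl, 2, seed = 5, weights = c(1, 0, 0))
  m <- match_pair_exact(paste0(rnd_str(40), ovl), paste0(ovl2, rnd_str(40)), 25)
  expect_lte(m$norm, 2 / 25)

  # reverting a mutated contig toward its source weakly decreases dist_C
  src <- contig_set(rnd_str(120))
  far <- contig_set(mutate_genome(src$contigs, 30, seed = 6))
  near <- contig_set(mutate_genome(src$contigs, 5, seed = 7))
  expect_lte(dist_C(src, near), dist_C(src, far) + 1e-9)
})
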