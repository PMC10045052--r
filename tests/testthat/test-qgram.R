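test_that("q-gram profiles count every substring", {
  p <- qgram_profile("acgt", 2)
  expect_equal(p$counts, c(ac = 1L, cg = 1L, gt = 1L))
  expect_equal(qgram_profile("aaaa", 2)$counts, c(aa = 3L))
  expect_length(qgram_profile("ac", 3)$counts, 0)
  expect_error(qgram_profile("acgt", 0), "at least 1")
  set.seed(21)
  for (i in 1:25) {
    s <- rnd_str(sample(0:30, 1)); q <- sample(1:4, 1)
    ora <- qgram_oracle(s, q)
    got <- qgram_profile(s, q)$counts
    expect_equal(got[order(names(got))], ora[order(names(ora))],
                 ignore_attr = FALSE)
    expect_equal(sum(got), max(0, nchar(s) - q + 1))
  }
})

test_that("q-gram distance is the L1 profile distance", {
  p <- qgram_profile("acgtacgt", 3)
  expect_equal(qgram_distance(p, p), 0)
  expect_equal(qgram_distance("acca", "acga", q = 2), 4)
  expect_equal(qgram_distance("acg", "", q = 2), 2)
  expect_error(qgram_distance(qgram_profile("acgt", 2),
                              qgram_profile("acgt", 3)), "different q")
})

test_that("q-gram distance is a pseudometric with genuine collisions", {
  set.seed(22)
  for (i in 1:25) {
    a <- rnd_str(sample(1:20, 1)); b <- rnd_str(sample(1:20, 1))
    cc <- rnd_str(sample(1:20, 1)); q <- sample(2:3, 1)
    expect_identical(qgram_distance(a, b, q = q), qgram_distance(b, a, q = q))
    expect_identical(qgram_distance(a, a, q = q), 0L)
    expect_lte(qgram_distance(a, b, q = q),
               qgram_distance(a, cc, q = q) + qgram_distance(cc, b, q = q))
  }
  # distinct strings sharing one 2-gram profile: zero distance
  expect_identical(qgram_distance("aca", "cac", q = 2), 0L)
})

test_that("the q-gram distance lower-bounds 2q times the edit distance", {
  set.seed(23)
  for (i in 1:120) {
    n1 <- sample(10:120, 1); n2 <- sample(10:120, 1)
    a <- rnd_str(n1)
    b <- if (runif(1) < 0.5) rnd_str(n2) else mutate_genome(a, sample(0:30, 1))
    d <- levenshtein(a, b)
    for (q in 2:4)
      expect_gte(d, qgram_distance(a, b, q = q) / (2 * q))
  }
})

test_that("sliding read windows equal from-scratch recomputation", {
  set.seed(24)
  for (i in 1:30) {
    r <- rnd_str(sample(3:12, 1))
    ctg <- rnd_str(sample(nchar(r):60, 1))
    q <- sample(2:3, 1)
    sw <- sliding_read_windows(r, ctg, q)
    expect_equal(nrow(sw), nchar(ctg) - nchar(r) + 1)
    for (k in seq_len(nrow(sw))) {
      w <- substr(ctg, sw$offset[k] + 1, sw$offset[k] + nchar(r))
      expect_identical(sw$distance[k], qgram_dist_oracle(r, w, q))
    }
  }
  expect_equal(nrow(sliding_read_windows("acgtac", "acg", 3)), 0)
  one <- sliding_read_windows("acgt", "acgt", 2)
  expect_equal(one$offset, 0L)
  expect_equal(one$distance, 0L)
})

test_that("sliding overlaps enumerate admissible configurations exactly", {
  set.seed(25)
  for (i in 1:20) {
    a <- rnd_str(sample(5:40, 1)); b <- rnd_str(sample(5:40, 1))
    ov <- sliding_overlaps(a, b, 5)
    for (k in seq_len(nrow(ov))) {
      sa <- substr(a, ov$a_start[k] + 1, ov$a_start[k] + ov$len[k])
      sb <- substr(b, ov$b_start[k] + 1, ov$b_start[k] + ov$len[k])
      expect_gte(ov$len[k], 5)
      expect_true(ov$q[k] %in% choose_q(ov$len[k]))
      expect_identical(ov$dist[k], qgram_dist_oracle(sa, sb, ov$q[k]))
    }
  }
  a <- strrep("acgt", 8)
  ov <- sliding_overlaps(a, a, 5)
  expect_true(any(ov$len == nchar(a) & ov$dist == 0))
  expect_equal(nrow(sliding_overlaps("acg", "tga", 5)), 0)
})

test_that("admissible q values follow the length-adaptive rule", {
  expect_equal(choose_q(256), c(4L, 5L))
  expect_equal(choose_q(20), c(2L, 3L))
  expect_equal(choose_q(1), 2L)
  expect_equal(choose_q(3), 2L)
  expect_equal(choose_q(4), 2L)
})

test_that("the normalized q-gram score is comparable across q", {
  expect_equal(normalized_qgram_score(0, 50, 3), 0)
  expect_equal(normalized_qgram_score(8, 64, 4), 0.03125)
  expect_equal(normalized_qgram_score(8, 64, 2),
               2 * normalized_qgram_score(8, 64, 4))
})
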