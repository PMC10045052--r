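make_pair <- function(m, seed, n = 1200, l = 30, cov = 3, frac = 0.5) {
  A <- random_genome(n, seed = seed)
  B <- mutate_genome(A, m, seed = seed + 1)
  TA <- sample_tuple("A", sample_reads(A, l, cov, seed = seed + 2),
                     sample_contigs(A, frac, min_len = 60, max_len = 200,
                                    seed = seed + 3))
  TB <- sample_tuple("B", sample_reads(B, l, cov, seed = seed + 4),
                     sample_contigs(B, frac, min_len = 60, max_len = 200,
                                    seed = seed + 5))
  list(A = TA, B = TB, genomes = c(A, B))
}

test_that("read-to-target distance is the minimum over both branches", {
  set.seed(91)
  ctg <- rnd_str(60)
  a <- substr(ctg, 11, 25)
  expect_equal(dist_rT(a, replicate(3, rnd_str(15)), ctg, 2), 0)
  # no contigs: reduces to the read-read minimum
  RB <- replicate(5, rnd_str(15))
  a2 <- rnd_str(15)
  expect_equal(dist_rT(a2, RB, character(), 2),
               min(vapply(RB, function(b) margin_gap_distance(a2, b, 2), 0L)))
  expect_error(dist_rT(a2, character(), character(), 2), "neither")
  for (i in 1:15) {
    t <- sample(0:3, 1)
    RB <- replicate(sample(1:6, 1), rnd_str(12))
    CB <- replicate(sample(1:3, 1), rnd_str(sample(12:50, 1)))
    a3 <- rnd_str(12)
    brute <- min(c(vapply(RB, function(b) margin_gap_distance(a3, b, t), 0L),
                   vapply(CB, function(ct) dist_rc(a3, ct, t, exact = TRUE),
                          0L)))
    expect_equal(dist_rT(a3, RB, CB, t), brute)
  }
})

test_that("the read-level pre-measure matches its manual assembly", {
  set.seed(92)
  p <- make_pair(80, seed = 920)
  l <- p$A$reads$l; cc <- p$A$reads$c
  t <- margin_budget(l, cc)
  M <- match_sets(p$A$contigs, p$B$contigs, "fast")
  RA_f <- filter_assembled_reads(p$A$reads, p$A$contigs)$reads
  RB_f <- filter_assembled_reads(p$B$reads, p$B$contigs)$reads
  CA_res <- residual_contigs(p$A$contigs, M)
  got <- dist_TT_minus_R(RA_f, CA_res, RB_f, p$B$contigs$contigs, l, cc)
  quotas <- floor(nchar(CA_res) * cc / l)
  den <- l * (length(RA_f) + sum(quotas))
  num <- sum(vapply(RA_f, function(a)
    dist_rT(a, RB_f, p$B$contigs$contigs, t), 0))
  bagB <- read_bag(RB_f, coverage = cc)
  num <- num + sum(vapply(CA_res, function(ar)
    as.numeric(dist_cR(ar, bagB, t = t)), 0))
  expect_equal(got, num / den)
  expect_gte(got, 0); expect_lte(got, 1)
  # nothing left to compare: convention 0
  expect_equal(dist_TT_minus_R(character(), character(), RB_f,
                               p$B$contigs$contigs, l, cc), 0)
})

test_that("the contig weight follows the covered-genome fraction", {
  m <- pasdist:::match_pair_row(1L, 1L, 0L, 500L, 0L, 500L, 0L)
  expect_equal(contig_weight(m, n_reads = 100, l = 10, c = 2), 1)
  expect_equal(contig_weight(pasdist:::empty_match_set(), 100, 10, 2), 0)
  over <- pasdist:::match_pair_row(1L, 1L, 0L, 2000L, 0L, 2000L, 0L)
  expect_equal(contig_weight(over, 100, 10, 2), 1)
  half <- pasdist:::match_pair_row(1L, 1L, 0L, 250L, 0L, 250L, 0L)
  expect_equal(contig_weight(half, 100, 10, 2), 0.5)
})

test_that("the pre-distance is the stated convex combination", {
  set.seed(93)
  p <- make_pair(60, seed = 930)
  bk <- dist_TT(p$A, p$B)
  expect_equal(bk$dist_TT, bk$w * bk$dist_C +
                 (1 - bk$w) * bk$dist_TT_minus_R)
  expect_gte(bk$dist_TT, 0); expect_lte(bk$dist_TT, 1)
  # no contigs: w = 0 endpoint, distance driven by reads alone
  TA0 <- sample_tuple("A", p$A$reads)
  TB0 <- sample_tuple("B", p$B$reads)
  bk0 <- dist_TT(TA0, TB0)
  expect_equal(bk0$w, 0)
  expect_equal(bk0$dist_TT, bk0$dist_TT_minus_R)
})

test_that("the final distance is symmetric, zero on identity and rescaled", {
  set.seed(94)
  p <- make_pair(70, seed = 940)
  TA2 <- sample_tuple("A2", p$A$reads, p$A$contigs)
  expect_equal(final_distance(p$A, TA2), 0)
  d1 <- final_distance(p$A, p$B)
  d2 <- final_distance(p$B, p$A)
  expect_equal(d1, d2)
  bk <- final_distance(p$A, p$B, breakdown = TRUE)
  scale <- max(p$A$reads$l * length(p$A$reads$reads) / p$A$reads$c,
               p$B$reads$l * length(p$B$reads$reads) / p$B$reads$c)
  expect_equal(bk$distance,
               0.5 * (bk$ab$dist_TT + bk$ba$dist_TT) * scale)
  expect_lte(d1, scale)
  expect_error(final_distance(sample_tuple("x", read_bag(character(), l = 30),
                                           p$A$contigs), p$B), "reads")
})

test_that("perfect full-genome contigs recover the exact distance scale", {
  set.seed(95)
  A <- random_genome(1500, seed = 950)
  B <- mutate_genome(A, 150, seed = 951)
  TA <- sample_tuple("A", sample_reads(A, 30, 3, seed = 952), contig_set(A))
  TB <- sample_tuple("B", sample_reads(B, 30, 3, seed = 953), contig_set(B))
  bk <- final_distance(TA, TB, breakdown = TRUE)
  expect_equal(bk$ab$w, 1)
  truth <- levenshtein(A, B)
  expect_lt(abs(bk$distance - truth) / truth, 0.10)
})

test_that("the distance matrix is consistent with pairwise calls", {
  set.seed(96)
  p1 <- make_pair(50, seed = 960)
  dup <- sample_tuple("Adup", p1$A$reads, p1$A$contigs)
  samples <- list(p1$A, p1$B, dup)
  m <- distance_matrix(samples)
  expect_equal(m["A", "Adup"], 0)
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 3), rownames(m)))
  expect_equal(m["A", "B"], final_distance(p1$A, p1$B))
  expect_error(distance_matrix(samples[1]), "at least two")
  expect_error(distance_matrix(list(p1$A, p1$A)), "unique")
})
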