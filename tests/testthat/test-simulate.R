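test_that("random genomes are seed-deterministic and uniform", {
  expect_identical(random_genome(100, seed = 1), random_genome(100, seed = 1))
  expect_equal(nchar(random_genome(100, seed = 2)), 100)
  g <- random_genome(100000, seed = 3)
  freqs <- table(strsplit(g, "")[[1]]) / 100000
  expect_true(all(abs(freqs - 0.25) < 0.01))
  expect_error(random_genome(0), "at least 1")
})

test_that("mutation never exceeds the requested edit budget", {
  A <- random_genome(300, seed = 4)
  expect_identical(mutate_genome(A, 0, seed = 5), A)
  expect_identical(mutate_genome(A, 7, seed = 6), mutate_genome(A, 7, seed = 6))
  set.seed(7)
  for (i in 1:15) {
    m <- sample(0:40, 1)
    B <- mutate_genome(A, m)
    expect_lte(levenshtein(A, B), m)
  }
  # substitution-only mutations keep the length
  expect_equal(nchar(mutate_genome(A, 10, seed = 8, weights = c(1, 0, 0))),
               nchar(A))
})

test_that("read sampling honors the coverage equation", {
  A <- random_genome(1000, seed = 9)
  bag <- sample_reads(A, 100, 2, seed = 10)
  expect_equal(length(bag$reads), 20)  # round(c |A| / l)
  expect_equal(bag$l, 100L)
  expect_equal(bag$c, 2)
  expect_true(all(vapply(bag$reads, function(r)
    grepl(r, A, fixed = TRUE), NA)))
  expect_identical(sample_reads(A, 100, 2, seed = 10)$reads, bag$reads)
  expect_error(sample_reads("acgt", 10, 1), "shorter")
})

test_that("contig extraction is non-overlapping and hits the target fraction", {
  expect_length(sample_contigs("acgtacgt", 0)$contigs, 0)
  A <- random_genome(10000, seed = 11)
  cs <- sample_contigs(A, 0.5, min_len = 200, max_len = 1000, seed = 12)
  total <- sum(nchar(cs$contigs))
  expect_gte(total, 5000 - 1000)
  expect_lte(total, 5000 + 1000)
  # each contig occurs in A and a disjoint placement exists
  pos <- lapply(cs$contigs, function(ct) {
    hits <- gregexpr(ct, A, fixed = TRUE)[[1]]
    expect_gte(hits[1], 1)
    c(hits[1], hits[1] + nchar(ct))  # unique for long random substrings
  })
  pos <- pos[order(vapply(pos, `[`, 0, 1))]
  starts <- vapply(pos, `[`, 0, 1)
  ends <- vapply(pos, `[`, 0, 2)
  expect_true(all(starts[-1] >= ends[-length(ends)]))
  expect_warning(sample_contigs(random_genome(100, seed = 13), 0.05,
                                min_len = 50, max_len = 60),
                 "min_len")
})

test_that("datasets carry exact reference distances with metric structure", {
  ds <- make_dataset(4, 600, mutations_per_edge = c(10, 60), l = 30, c = 3,
                     contig_fraction = 0.5, seed = 14,
                     min_contig = 60, max_contig = 150)
  expect_length(ds$samples, 4)
  ref <- ds$reference
  expect_equal(ref, t(ref))
  expect_equal(unname(diag(ref)), rep(0, 4))
  labs <- rownames(ref)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(ref[i, j],
                 levenshtein(ds$genomes[[labs[i]]], ds$genomes[[labs[j]]]))
    for (k in 1:4) expect_lte(ref[i, j], ref[i, k] + ref[k, j])
  }
  # identical twins: zero mutations along every edge
  twins <- make_dataset(3, 300, mutations_per_edge = c(0, 0), l = 20, c = 2,
                        contig_fraction = 0, seed = 15)
  expect_true(all(twins$reference == 0))
  # determinism of the whole dataset
  ds2 <- make_dataset(4, 600, mutations_per_edge = c(10, 60), l = 30, c = 3,
                      contig_fraction = 0.5, seed = 14,
                      min_contig = 60, max_contig = 150)
  expect_identical(ds$genomes, ds2$genomes)
  expect_identical(ds$samples[[1]]$reads$reads, ds2$samples[[1]]$reads$reads)
})
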