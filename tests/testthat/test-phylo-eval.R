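tree_from_text <- function(txt) ape::read.tree(text = txt)

test_that("neighbor joining recovers additive trees exactly", {
  # ((A:1,B:2):1,(C:3,D:4)) -> path-length (additive) matrix
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- neighbor_joining(d)
  expect_equal(ape::dist.topo(ape::unroot(tr),
                              ape::unroot(tree_from_text(
                                "((A:1,B:2):1,(C:3,D:4):0);"))), 0,
               ignore_attr = TRUE)
  expect_equal(unname(ape::cophenetic.phylo(tr)[rownames(d), rownames(d)]),
               unname(d), tolerance = 1e-9)

  # two taxa: one edge split evenly
  d2 <- dist_matrix(matrix(c(0, 4, 4, 0), 2), c("x", "y"))
  t2 <- neighbor_joining(d2)
  expect_equal(sum(t2$edge.length), 4)

  # three taxa: closed-form half-sum branch lengths
  d3 <- dist_matrix(matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3),
                    c("x", "y", "z"))
  t3 <- neighbor_joining(d3)
  cps <- ape::cophenetic.phylo(t3)[c("x", "y", "z"), c("x", "y", "z")]
  expect_equal(unname(cps), unname(as.matrix(d3)), tolerance = 1e-9)

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "symmetric")
})

test_that("neighbor joining is exact on random additive matrices", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    d <- ape::cophenetic.phylo(tr)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    est <- neighbor_joining(dist_matrix(d))
    expect_equal(ape::dist.topo(ape::unroot(est), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("Newick output round trips and quotes awkward labels", {
  t2 <- neighbor_joining(dist_matrix(matrix(c(0, 1, 1, 0), 2),
                                     c("A", "B")))
  s <- write_newick(t2)
  expect_match(s, "^\\(A:0\\.5,B:0\\.5\\);$")

  set.seed(102)
  for (i in 1:8) {
    tr <- ape::rtree(10)
    f <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, f)
    back <- ape::read.tree(f)
    expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
  }

  tr <- ape::rtree(3)
  tr$tip.label <- c("taxon one", "t2", "t3")
  expect_match(write_newick(tr), "'taxon one'", fixed = TRUE)
})

test_that("matrix correlation uses the upper triangle and flags degeneracy", {
  set.seed(103)
  v <- matrix(runif(16, 1, 9), 4); v <- v + t(v); diag(v) <- 0
  m <- dist_matrix(v, letters[1:4])
  expect_equal(pearson_matrices(m, m), 1)
  expect_equal(pearson_matrices(m, dist_matrix(2 * v + 3 - 3 * diag(4),
                                               letters[1:4])), 1)
  const <- dist_matrix(matrix(1, 4, 4) - diag(4), letters[1:4])
  expect_warning(r <- pearson_matrices(const, m), "equidistant")
  expect_true(is.na(r))
  expect_error(pearson_matrices(m, dist_matrix(v, letters[5:8])), "labels")
})

test_that("tree cutting yields the requested number of clusters", {
  tr <- tree_from_text("(((A:1,B:1):8,(C:1,D:1):8):1,(E:1,F:1):9);")
  expect_equal(unname(cut_tree(tr, 1)), rep(1L, 6))
  expect_equal(length(unique(cut_tree(tr, 6))), 6)
  c2 <- cut_tree(tr, 2)
  expect_equal(length(unique(c2)), 2)
  # the long central edge separates {A,B,C,D} from {E,F}
  expect_equal(length(unique(c2[c("A", "B", "C", "D")])), 1)
  expect_equal(length(unique(c2[c("E", "F")])), 1)
  expect_true(c2[["A"]] != c2[["E"]])
  c4 <- cut_tree(tr, 4)
  expect_equal(length(unique(c4)), 4)
  expect_error(cut_tree(tr, 7), "between 1")
})

test_that("the Fowlkes-Mallows index counts co-clustered pairs", {
  c1 <- setNames(c(1L, 1L, 2L, 2L), LETTERS[1:4])  # AB | CD
  c2 <- setNames(c(1L, 2L, 1L, 2L), LETTERS[1:4])  # AC | BD
  c3 <- setNames(c(1L, 1L, 1L, 2L), LETTERS[1:4])  # ABC | D
  expect_equal(fowlkes_mallows(c1, c1), 1)
  expect_equal(fowlkes_mallows(c1, c2), 0)
  # TP = 1 (pair AB), FP = 1 (CD), FN = 2 (AC, BC): B = 1/sqrt(2*3)
  expect_equal(fowlkes_mallows(c1, c3), 1 / sqrt(6))
  ones <- setNames(rep(1L, 4), LETTERS[1:4])
  singl <- setNames(1:4, LETTERS[1:4])
  expect_equal(fowlkes_mallows(ones, ones), 1)
  expect_equal(fowlkes_mallows(singl, singl), 1)
  expect_error(fowlkes_mallows(c1, setNames(1:4, LETTERS[2:5])), "labels")
})

test_that("the triplet distance counts differing induced topologies", {
  t1 <- tree_from_text("((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- tree_from_text("((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(triplets_distance(t1, t1), 0)
  expect_equal(triplets_distance(t1, t2), 4)
  star <- tree_from_text("(A,B,C,D);")
  expect_equal(triplets_distance(star, star), 0)
  expect_equal(triplets_distance(star, t1), 4)  # resolved vs unresolved
  set.seed(104)
  for (i in 1:8) {
    a <- ape::rtree(7); b <- ape::rtree(7)
    td <- triplets_distance(a, b)
    expect_gte(td, 0)
    expect_lte(td, choose(7, 3))
    expect_equal(triplets_distance(a, a), 0)
  }
  expect_error(triplets_distance(t1, tree_from_text("((A,B),(C,E));")),
               "leaf set")
})
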