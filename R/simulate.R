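## Synthetic-data generator: random genomes, point-mutation evolution along
## a tree, i.i.d. uniform read sampling, non-overlapping contig extraction,
## and exact ground-truth distance matrices.  All functions are
## seed-deterministic; the defaults are the simulation conditions used
## throughout the package's own evaluation.

local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random genome
#'
#' i.i.d. uniform string over `{a, c, g, t}`.
#'
#' @param n Length (>= 1).
#' @param seed Optional seed; the caller's RNG state is untouched.
#' @return Single string of length `n`.
#' @export
random_genome <- function(n, seed = NULL) {
  if (n < 1) stop("genome length must be at least 1")
  local_seed(seed,
    paste(sample(c("a", "c", "g", "t"), n, replace = TRUE), collapse = ""))
}

#' Apply point mutations to a genome
#'
#' Applies `m` point edits at uniformly random positions; by default 80%
#' substitutions (to one of the three other bases), 10% insertions and 10%
#' deletions, reflecting that the target of the estimation is the number of
#' point mutations.  A deletion drawn on an empty string is re-sampled as
#' an insertion.  Guarantees `levenshtein(A, result) <= m`.
#'
#' @param A Genome string.
#' @param m Number of edits (>= 0).
#' @param seed Optional seed.
#' @param weights Proportions `c(sub, ins, del)`, normalized internally.
#' @return Mutated string.
#' @export
mutate_genome <- function(A, m, seed = NULL,
                          weights = c(sub = 0.8, ins = 0.1, del = 0.1)) {
  stopifnot(m >= 0, length(weights) == 3, all(weights >= 0))
  bases <- c("a", "c", "g", "t")
  local_seed(seed, {
    s <- strsplit(A, "")[[1]]
    for (i in seq_len(m)) {
      op <- sample(c("sub", "ins", "del"), 1, prob = weights)
      if (op == "del" && length(s) == 0) op <- "ins"
      if (op == "sub" && length(s) == 0) op <- "ins"
      if (op == "sub") {
        p <- sample.int(length(s), 1)
        s[p] <- sample(setdiff(bases, s[p]), 1)
      } else if (op == "ins") {
        p <- sample.int(length(s) + 1, 1)  # insert before position p
        s <- append(s, sample(bases, 1), after = p - 1)
      } else {
        p <- sample.int(length(s), 1)
        s <- s[-p]
      }
    }
    paste(s, collapse = "")
  })
}

#' Sample a read bag from a genome
#'
#' `round(c * |A| / l)` reads of length `l`, each starting at a uniformly
#' random position, drawn i.i.d. with replacement (duplicates preserved).
#'
#' @param A Genome string with `|A| >= l`.
#' @param l Read length.
#' @param c Fold coverage.
#' @param seed Optional seed.
#' @return A [read_bag()] carrying `l` and `c`.
#' @export
sample_reads <- function(A, l, c, seed = NULL) {
  n <- nchar(A)
  if (n < l) stop("genome shorter than the read length")
  count <- round(c * n / l)
  local_seed(seed, {
    starts <- sample.int(n - l + 1, count, replace = TRUE)
    read_bag(substring(A, starts, starts + l - 1), l = l, coverage = c)
  })
}

#' Extract non-overlapping contigs from a genome
#'
#' Emulates a partial assembly: non-overlapping substrings with lengths
#' uniform in `[min_len, max_len]`, totaling about `fraction * |A|` (within
#' one contig length), separated by random gaps, returned in random order
#' so that genome position does not leak through ordering.
#'
#' @param A Genome string.
#' @param fraction Target covered fraction in `[0, 1]`.
#' @param min_len,max_len Contig length bounds (defaults 200 and 1000 nt,
#'   typical of draft assemblies of short genomes).
#' @param seed Optional seed.
#' @return A [contig_set()]; empty (with a warning) when infeasible.
#' @export
sample_contigs <- function(A, fraction, min_len = 200L, max_len = 1000L,
                           seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1, min_len >= 1, max_len >= min_len)
  n <- nchar(A)
  if (fraction == 0) return(contig_set())
  target <- fraction * n
  if (target < min_len) {
    warning("target contig length below min_len; returning no contigs")
    return(contig_set())
  }
  local_seed(seed, {
    lens <- integer(0)
    while (sum(lens) < target) {
      nxt <- sample(seq.int(min_len, max_len), 1)
      if (sum(lens) + nxt > n) {
        if (length(lens) == 0) nxt <- min(n, max_len)
        else break
      }
      lens <- c(lens, nxt)
      if (sum(lens) + min_len > n) break
    }
    k <- length(lens)
    free <- n - sum(lens)
    # distribute the free space as k+1 random gaps
    cuts <- sort(sample.int(free + 1, k, replace = TRUE) - 1L)
    gaps <- diff(c(0L, cuts, free))
    starts <- cumsum(gaps[seq_len(k)]) + c(0L, cumsum(lens))[seq_len(k)]
    contigs <- substring(A, starts + 1, starts + lens)
    contig_set(sample(contigs))
  })
}

#' Random rooted binary topology
#'
#' Successive random attachment; used to evolve simulated genomes.
#'
#' @param labels Leaf labels.
#' @return Rooted binary `phylo` tree without branch lengths.
#' @keywords internal
random_topology <- function(labels) {
  tr <- ape::rtree(length(labels), rooted = TRUE, br = NULL)
  tr$tip.label <- sample(labels)
  tr
}

#' Simulate a full dataset
#'
#' Evolves genomes along a random rooted binary tree: the root genome is
#' uniform random, and each edge applies a uniformly drawn number of point
#' mutations from `mutations_per_edge`.  Each leaf becomes one sample with
#' an i.i.d. read bag and, when `contig_fraction > 0`, a non-overlapping
#' contig set.  The reference matrix holds the exact pairwise Levenshtein
#' distances of the true leaf genomes.
#'
#' @param n_samples Number of leaves (>= 2).
#' @param genome_len Root genome length (nt).
#' @param mutations_per_edge Length-2 range of per-edge mutation counts.
#' @param l Read length.
#' @param c Fold coverage.
#' @param contig_fraction Fraction of each genome covered by contigs.
#' @param seed Seed for the whole dataset.
#' @param min_contig,max_contig Contig length bounds.
#' @return List with `samples` (list of [sample_tuple()]), `reference`
#'   (exact distance matrix), `tree` (the generating topology with the edge
#'   mutation counts as branch lengths) and `genomes` (named character).
#' @export
make_dataset <- function(n_samples, genome_len,
                         mutations_per_edge = c(50, 400), l = 100L, c = 5,
                         contig_fraction = 0.6, seed = NULL,
                         min_contig = 200L, max_contig = 1000L) {
  if (n_samples < 2) stop("need at least two samples")
  labels <- sprintf("s%02d", seq_len(n_samples))
  local_seed(seed, {
    tr <- random_topology(labels)
    n_tip <- length(tr$tip.label)
    n_node <- n_tip + tr$Nnode
    root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
    genomes <- vector("character", n_node)
    genomes[root] <- random_genome(genome_len)
    m_edge <- sample(seq.int(mutations_per_edge[1], mutations_per_edge[2]),
                     nrow(tr$edge), replace = TRUE)
    kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
    queue <- root
    while (length(queue) > 0) {
      node <- queue[1]; queue <- queue[-1]
      for (e in kids[[as.character(node)]]) {
        child <- tr$edge[e, 2]
        genomes[child] <- mutate_genome(genomes[node], m_edge[e])
        if (child > n_tip) queue <- c(queue, child)
      }
    }
    tr$edge.length <- m_edge
    leaf_genomes <- setNames(genomes[seq_len(n_tip)], tr$tip.label)
    leaf_genomes <- leaf_genomes[labels]
    samples <- lapply(labels, function(lb) {
      g <- leaf_genomes[[lb]]
      bag <- sample_reads(g, l, c)
      ctg <- if (contig_fraction > 0)
        sample_contigs(g, contig_fraction, min_contig, max_contig)
      else contig_set()
      sample_tuple(lb, bag, ctg)
    })
    reference <- dist_matrix(cpp_lev_matrix(unname(leaf_genomes)), labels)
    list(samples = samples, reference = reference, tree = tr,
         genomes = leaf_genomes)
  })
}

#' Write a dataset to a directory
#'
#' FASTQ reads and FASTA contigs and genomes per sample, the PHYLIP
#' reference matrix, the generating tree in Newick, and a JSON manifest of
#' all parameters for reproducibility.
#'
#' @param ds A dataset from [make_dataset()].
#' @param dir Output directory (created if missing).
#' @param params Named list echoed into the manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, params = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in ds$samples) {
    write_fastq(s$reads, file.path(dir, paste0(s$label, ".fastq")))
    if (length(s$contigs$contigs) > 0) {
      ctg <- setNames(s$contigs$contigs,
                      sprintf("%s_contig%d", s$label,
                              seq_along(s$contigs$contigs)))
      write_fasta(ctg, file.path(dir, paste0(s$label, "_contigs.fasta")))
    }
  }
  write_fasta(ds$genomes, file.path(dir, "genomes.fasta"))
  write_phylip(ds$reference, file.path(dir, "reference.phy"))
  write_newick(ds$tree, file.path(dir, "true_tree.nwk"))
  manifest <- c(list(labels = vapply(ds$samples, function(s) s$label,
                                     character(1)),
                     l = ds$samples[[1]]$reads$l,
                     coverage = ds$samples[[1]]$reads$c),
                params)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
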