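## Domain types and sequence I/O.

normalize_seq <- function(x) tolower(x)

check_alphabet <- function(x, ids, what = "sequence") {
  bad <- grepl("[^acgtn]", x)
  if (any(bad)) {
    stop(sprintf("%s '%s' contains characters outside {a,c,g,t,n}",
                 what, ids[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

#' Create a read bag
#'
#' A read bag holds a multiset of fixed-length reads together with the read
#' length `l` and the fold coverage `c` (the average number of reads covering
#' a genome position, `c = l * |R| / |A|`).  Duplicate reads are preserved:
#' reads are modeled as sampled with replacement.
#'
#' @param reads Character vector of reads (lowercase `acgt`).
#' @param l Read length; defaults to the common length of `reads`.
#' @param coverage Fold coverage `c`; may be `NA` until known.
#' @return An object of class `read_bag` with fields `reads`, `l`, `c`.
#' @export
read_bag <- function(reads, l = NULL, coverage = NA_real_) {
  reads <- normalize_seq(as.character(reads))
  if (is.null(l)) {
    if (length(reads) == 0) stop("cannot infer read length from an empty bag")
    l <- nchar(reads[1])
  }
  l <- as.integer(l)
  if (length(reads) > 0) {
    lens <- unique(nchar(reads))
    if (length(lens) > 1 || lens[1] != l) {
      stop(sprintf("reads must all have length %d (observed lengths: %s)",
                   l, paste(sort(unique(c(lens))), collapse = ", ")))
    }
  }
  if (!is.na(coverage) && coverage <= 0) stop("coverage must be positive")
  structure(list(reads = reads, l = l, c = as.numeric(coverage)),
            class = "read_bag")
}

#' @export
print.read_bag <- function(x, ...) {
  cat(sprintf("read_bag: %d reads of length %d, coverage %s\n",
              length(x$reads), x$l,
              if (is.na(x$c)) "unset" else format(x$c)))
  invisible(x)
}

#' Create a contig set
#'
#' Contigs are putative substrings of the underlying genome, assumed not to
#' overlap each other in the genome (verifiable only in simulation).
#'
#' @param contigs Character vector of contig sequences.
#' @return An object of class `contig_set`.
#' @export
contig_set <- function(contigs = character()) {
  contigs <- normalize_seq(as.character(contigs))
  if (any(nchar(contigs) == 0)) stop("contigs must be non-empty strings")
  structure(list(contigs = contigs), class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("contig_set: %d contigs, total length %d\n",
              length(x$contigs), sum(nchar(x$contigs))))
  invisible(x)
}

#' Create a sample tuple
#'
#' Bundles one sample's read bag and contig set under a label.  At least one
#' of the two parts must be non-empty.
#'
#' @param label Sample label.
#' @param reads A [read_bag()].
#' @param contigs A [contig_set()]; defaults to empty.
#' @return An object of class `sample_tuple`.
#' @export
sample_tuple <- function(label, reads, contigs = contig_set()) {
  stopifnot(inherits(reads, "read_bag"), inherits(contigs, "contig_set"))
  if (length(reads$reads) == 0 && length(contigs$contigs) == 0)
    stop("a sample needs at least one read or contig")
  structure(list(label = as.character(label), reads = reads,
                 contigs = contigs),
            class = "sample_tuple")
}

#' @export
print.sample_tuple <- function(x, ...) {
  cat(sprintf("sample '%s': %d reads (l=%d, c=%s), %d contigs\n",
              x$label, length(x$reads$reads), x$reads$l,
              if (is.na(x$reads$c)) "unset" else format(x$reads$c),
              length(x$contigs$contigs)))
  invisible(x)
}

#' Read a FASTA file
#'
#' Sequences are lowercased; records containing characters outside
#' `{a,c,g,t,n}` after lowercasing are rejected with an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop(sprintf("failed to parse FASTA file '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  if (length(set) == 0)
    stop(sprintf("FASTA file '%s' contains no records", path), call. = FALSE)
  seqs <- normalize_seq(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  names(seqs) <- ids
  check_alphabet(seqs, ids, "FASTA record")
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read a FASTQ file into a read bag
#'
#' Quality strings are discarded.  With `drop_ambiguous` (the default), reads
#' containing `n` are dropped: the model treats reads as exact substrings of
#' the genome.  All retained reads must share one length.
#'
#' @param path Path to a FASTQ file.
#' @param drop_ambiguous Drop reads containing `n`?
#' @return A [read_bag()] with coverage unset.
#' @export
read_fastq <- function(path, drop_ambiguous = TRUE) {
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fastq"),
                  error = function(e)
                    stop(sprintf("failed to parse FASTQ file '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  reads <- normalize_seq(as.character(set))
  check_alphabet(reads, names(set), "FASTQ record")
  if (drop_ambiguous) reads <- reads[!grepl("n", reads, fixed = TRUE)]
  lens <- unique(nchar(reads))
  if (length(lens) > 1)
    stop(sprintf("mixed read lengths in '%s': %d and %d", path,
                 lens[1], lens[2]), call. = FALSE)
  read_bag(unname(reads), l = if (length(reads)) lens[1] else NULL)
}

#' Write a read bag to a FASTQ file
#'
#' Qualities are written as constant `I` (the model carries none).
#'
#' @param bag A [read_bag()].
#' @param path Output path.
#' @export
write_fastq <- function(bag, path) {
  stopifnot(inherits(bag, "read_bag"))
  n <- length(bag$reads)
  lines <- character(4 * n)
  if (n > 0) {
    idx <- seq_len(n)
    lines[4 * idx - 3] <- sprintf("@read%d", idx)
    lines[4 * idx - 2] <- bag$reads
    lines[4 * idx - 1] <- "+"
    lines[4 * idx] <- strrep("I", bag$l)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load one sample from files
#'
#' If `coverage` is not supplied it is estimated as `c = l * |R| / |A-hat|`
#' where `|A-hat|` is the total contig length standing in for the unknown
#' genome length; this requires contigs to be present.
#'
#' @param label Sample label.
#' @param reads_path FASTQ file of reads.
#' @param contigs_path Optional FASTA file of contigs.
#' @param coverage Optional fold coverage.
#' @return A [sample_tuple()].
#' @export
load_sample <- function(label, reads_path, contigs_path = NULL,
                        coverage = NULL) {
  bag <- read_fastq(reads_path)
  contigs <- if (is.null(contigs_path)) contig_set()
             else contig_set(unname(read_fasta(contigs_path)))
  if (is.null(coverage)) {
    total <- sum(nchar(contigs$contigs))
    if (total == 0)
      stop("no coverage given and no contigs to estimate it from",
           call. = FALSE)
    coverage <- bag$l * length(bag$reads) / total
  }
  bag$c <- as.numeric(coverage)
  if (bag$c <= 0) stop("coverage must be positive")
  sample_tuple(label, bag, contigs)
}

#' Construct a validated distance matrix
#'
#' @param values Square numeric matrix.
#' @param labels Sample labels (defaults to existing dimnames).
#' @return Symmetric matrix with zero diagonal and labels as dimnames.
#' @export
dist_matrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("distance matrix must be square")
  if (is.null(labels) || length(labels) != n)
    stop("labels must match matrix dimension")
  if (anyDuplicated(labels)) stop("duplicate labels in distance matrix")
  if (any(values < 0)) stop("distances must be non-negative")
  if (any(abs(values - t(values)) > 1e-9)) stop("matrix must be symmetric")
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal must be zero")
  dimnames(values) <- list(labels, labels)
  values
}

#' Write a square PHYLIP distance matrix
#'
#' @param matrix Distance matrix (see [dist_matrix()]).
#' @param path Output path.
#' @export
write_phylip <- function(matrix, path) {
  matrix <- dist_matrix(matrix)
  labels <- rownames(matrix)
  if (any(grepl("\\s", labels)))
    stop("PHYLIP labels must not contain whitespace")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(matrix)), con)
  for (i in seq_len(nrow(matrix))) {
    writeLines(paste(formatC(labels[i], width = -10),
                     paste(sprintf("%.6f", matrix[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path Path to a PHYLIP square distance matrix.
#' @return A validated distance matrix.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 1)
    stop(sprintf("malformed PHYLIP matrix in '%s'", path))
  labels <- character(n)
  values <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    labels[i] <- parts[1]
    values[i, ] <- as.numeric(parts[-1][seq_len(n)])
  }
  dist_matrix(values, labels)
}
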