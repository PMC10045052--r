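# pasdist

Reference-free estimation of genome distances from sequencing reads and
partially assembled contigs, and the phylogenies built from them.

## The problem

Building a phylogenetic tree normally requires the genome sequences, but
sequencing projects often stop short of them: what is published is a bag
of short reads per sample, sometimes with a draft assembly — a set of
contigs covering part of the genome.  pasdist estimates the pairwise
**Levenshtein (edit) distance** between the underlying genomes directly
from this material, without a reference genome, without finishing the
assembly, and without reducing everything to k-mer statistics.  Because a
point mutation changes the edit distance by at most one, the estimate
reads as the number of point mutations separating two organisms — the
quantity a phylogeny wants.  The intended scale is viral and short
bacterial genomes; the intended user is anyone clustering strains from
read sets or draft assemblies.

## The method in brief

For samples $T_A=(R_A,C_A)$ and $T_B=(R_B,C_B)$ (read bag + contig set),
pasdist matches the material four ways and combines the results:

* **read–read**: each read meets its closest read under a margin-tolerant
  edit distance — the first $t=\lfloor\frac12(l/c-1)\rfloor$ leading and
  trailing gaps are free, absorbing the random placement of reads
  (Monge–Elkan aggregation);
* **contig–contig**: each contig pair is matched by the substring pair
  (overlap or containment, ≥ 20 nt) minimizing the post-normalized
  distance $\mathrm{edit}/\max(|\alpha^*|,|\beta^*|)$; per contig, a
  weighted-interval-scheduling step keeps a non-overlapping set of
  matches, giving the contig-set distance $\mathrm{dist_C}$;
* **read–contig**: each leftover read meets the best window of each
  contig;
* **contig–reads**: each unmatched contig substring of length $L$ meets
  its $\lfloor Lc/l \rfloor$ closest reads.

Reads already assembled into the sample's own contigs are removed first
(multi-pattern exact search), and contig parts matched contig-to-contig
are not matched again against reads.  The read-level facets combine into a
$[0,1]$ pre-measure, mixed with $\mathrm{dist_C}$ by the weight
$w=\min(1, |\mathrm{match}|\,c/(|R_A|\,l))$ — the genome fraction covered
by matched contigs — then symmetrized and rescaled by
$l\max(|R_A|,|R_B|)/c$ to edit-distance units.  With no contigs at all the
estimator runs on reads alone.

All matching is accelerated by q-gram (k-mer) profiles through the bound
$\mathrm{dist}(A,B)\ge \mathrm{dist}_q(A,B)/(2q)$: sliding-window profile
updates rank candidates in linear time, and exact dynamic programming is
spent only where the bound admits improvement — so the fast read-level
paths return exactly the exhaustive minima.  Neighbor joining, Newick
output, tree cutting, the Fowlkes–Mallows index and the triplet distance
close the loop from distance matrix to evaluated phylogeny, and a
simulator generates reads, contigs and exact reference distances for
controlled experiments.  See the methods vignette
(`vignettes/pasdist-methods.Rmd`) for the model, conventions and design
decisions.

## A worked example

Six simulated samples, 3 kb genomes, reads of length 100 at coverage 5,
contigs covering 60%:

```r
library(pasdist)

ds  <- make_dataset(n_samples = 6, genome_len = 3000,
                    mutations_per_edge = c(40, 200), l = 100, c = 5,
                    contig_fraction = 0.6, seed = 11)
est <- distance_matrix(ds$samples)
round(est)
#>     s01 s02 s03 s04 s05 s06
#> s01   0 472 346 519 531 468
#> s02 472   0 542 376 579 550
#> s03 346 542   0 533 561 563
#> s04 519 376 533   0 570 564
#> s05 531 579 561 570   0 206
#> s06 468 550 563 564 206   0

pearson_matrices(est, ds$reference)
#> [1] 0.9510077

tree <- neighbor_joining(est)
triplets_distance(tree, ds$tree)
#> [1] 0
```

The estimated matrix overshoots the exact reference (for example 206
against a true 161 for the closest pair `s05`–`s06` — unsampled genome
parts and imperfect matches add noise on top of the true differences), but
it preserves the relative structure: the correlation with the exact
Levenshtein reference is 0.95 here, and neighbor joining recovers the
generating topology exactly (triplet distance 0).

The same pipeline is available from a shell via `inst/cli/pasdist`
(`simulate`, `distmat`, `tree`, `evaluate`).

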