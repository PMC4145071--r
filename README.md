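# subotu

Subsampled open-reference OTU picking for marker-gene (e.g. 16S rRNA)
amplicon surveys, in R.

Microbial community analysis starts by clustering amplicon reads into
operational taxonomic units (OTUs): groups of reads within a percent
identity *s* (conventionally 97%) of a centroid sequence. The classic
strategies trade off completeness against parallelism — *de novo*
clustering keeps every read but is serial; *closed-reference* clustering
is embarrassingly parallel but discards reads that miss the reference
database; *open-reference* clustering chains the two, inheriting the
serial de novo tail. **Subsampled open-reference picking** restructures
the open-reference protocol: after the parallel closed-reference pass at
identity *s*, only a small random fraction *n* (default 0.1%) of the
failures is clustered de novo; the centroids of those clusters act as a
new reference so the remaining failures can again be assigned in
parallel, and a final de novo pass cleans up what is left. The output
partitions OTUs into three provenance tiers — *reference*,
*new reference* (`New.ReferenceOTU<i>`) and *clean-up*
(`New.CleanUpReferenceOTU<i>`) — and the new centroids can be folded back
into the reference so later runs reuse the same OTU ids (iterative
picking). At *n* = 1 (and at *n* = 0) the protocol reduces exactly to
classic open-reference picking.

The package provides:

* a greedy centroid clustering engine (k-mer candidate ranking,
  uclust-style `max_accepts`/`max_rejects` early termination, semi-global
  alignment identity; `slow` 20/500/20/12 and `fast` 1/8/8/8 presets),
  with the pairwise-alignment core in C++;
* the four picking workflows (`pick_de_novo`, `pick_closed_reference`,
  `pick_classic_open_reference`, `pick_subsampled_open_reference`), an
  optional 60%-identity contaminant prefilter, and iterative reference
  expansion;
* OTU-table construction, rarefaction, taxonomic collapse and merging;
* Faith's PD, unweighted/weighted UniFrac, and a concordance report
  (alpha Pearson r, UniFrac Mantel r/p, taxonomic-profile r) for
  comparing picking runs;
* a synthetic benchmark generator (reference centroids with phylogeny and
  taxonomy, planted novel lineages, multi-sample reads along an occupancy
  gradient, verified non-marker contaminants) so everything runs with no
  external databases.

## Worked example

Generate the standard synthetic benchmark (60 reference + 20 novel
lineages, 12 samples x 2,000 reads, 2% contaminants), run subsampled and
classic open-reference picking, and compare their summaries (about a
minute on one CPU):

```r
library(subotu)

bench  <- make_benchmark(sim_config())
params <- workflow_params(seed = 7)

sub <- pick_subsampled_open_reference(bench$reads, bench$reference, params)
sub
#> otu_result: 562 OTUs, 24000 reads in table, 0 prefilter discards, 0 unmatched
#>
#>       cleanup new_reference     reference
#>           497             5            60

classic <- pick_classic_open_reference(bench$reads, bench$reference, params)

sub$table_full     <- set_taxonomy(sub$table_full, bench$taxonomy)
classic$table_full <- set_taxonomy(classic$table_full, bench$taxonomy)
tree_sub     <- extend_tree_with_new_otus(bench$tree, sub, bench$truth)
tree_classic <- extend_tree_with_new_otus(bench$tree, classic, bench$truth)

compare_runs(sub, classic, tree_sub, tree_classic, depth = 1000, seed = 1)
#> Concordance report (12 samples, depth 1000)
#> alpha diversity Pearson r:
#>   observed_otus          0.9954
#>   faith_pd               0.9982
#> beta diversity Mantel (1000 permutations):
#>   unweighted_unifrac     r = 0.9972, p = 0.000999
#>   weighted_unifrac       r = 0.9999, p = 0.000999
#> taxonomic profile Pearson r:
#>   rank2                  1.0000
#>   rank6                  1.0000
```

Reading the output: both runs keep all 24,000 reads (open-reference
methods cluster everything; the closed-reference workflow instead records
its failures). The subsampled run assigns the same reads to the same 60
reference OTUs as the classic run, mints 5 new-reference OTUs from its
0.1% failure subsample and 497 clean-up OTUs (mostly the one-off
contaminant reads); the classic run clusters the same failures in a
single de novo pass into 502 OTUs. Although the two runs' new OTU
boundaries may differ slightly, every downstream summary a study would
interpret — per-sample richness and phylogenetic diversity, UniFrac
community distances, taxonomic profiles — is correlated at r ≥ 0.99
here, which is the method's core claim. The filtered table
(`sub$table_filtered`, minimum OTU size 2) additionally drops singleton
OTUs.

Command-line wrappers over the same functions live in `inst/scripts/`:
`pick-otus.R`, `compare-runs.R` and `make-benchmark.R`
(`Rscript inst/scripts/pick-otus.R --method subsampled-open --input
reads.fna --reference ref.fna --output out/`).

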