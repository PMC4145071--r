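---
title: "Subsampled open-reference OTU picking: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subsampled open-reference OTU picking: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(subotu)
```

## The problem

Marker-gene surveys (16S rRNA amplicons and relatives) summarize microbial
communities by clustering reads into operational taxonomic units (OTUs):
groups of reads within a percent-identity threshold *s* (conventionally
97%) of a centroid sequence. Three picking strategies are standard:

* **de novo** — centroids are minted greedily from the reads themselves.
  No reference needed, but the process is inherently serial: every read
  must be able to see OTUs founded by earlier reads.
* **closed-reference** — reads are matched only against a pre-existing
  centroid database. Embarrassingly parallel (reads can be split across
  workers because the centroid set is fixed), and OTUs come with curated
  taxonomy and a phylogeny, but reads with no database match are thrown
  away, so novel diversity is invisible.
* **open-reference** — a closed-reference pass, then de novo clustering of
  the failures. All reads are kept, but the serial de novo tail dominates
  the runtime when many reads miss the reference.

**Subsampled open-reference picking** restructures the open-reference
protocol so that most of the failure clustering is also parallel:

1. closed-reference assignment of all reads against the reference at *s*
   (the *reference OTUs*);
2. a small random fraction *n* (default 0.1%) of the failures is clustered
   de novo; its centroids mint the *new reference OTUs*
   (`New.ReferenceOTU<i>`);
3. the remaining failures are clustered closed-reference — hence in
   parallel — against those new centroids;
4. reads that still match nothing are clustered de novo into the
   *clean-up OTUs* (`New.CleanUpReferenceOTU<i>`);
5. the three tiers are merged into one OTU-by-sample table, emitted both
   in full and filtered at a minimum OTU size *c*.

At `subsample_fraction = 1` the whole failure set is clustered de novo in
one pass and the protocol *is* classic open-reference picking (the package
tests this partition-for-partition); at `subsample_fraction = 0` the
subsample is empty, every failure falls through to the clean-up pass, and
the protocol again degenerates to the classic one. New-tier centroids can
be appended to the reference with `iterative_update_reference()`, so later
runs assign matching reads to the *same* OTU ids — stable OTU definitions
across sequencing runs.

## The clustering engine

The engine is a greedy centroid clusterer in the uclust mold. For each
query read, candidate centroids are ranked by the number of distinct
k-mers (`wordlength`, default 12) they share with the query, ties broken
by centroid insertion order. Candidates are aligned in rank order until
`max_accepts` candidates have met the identity threshold or `max_rejects`
have failed it; among accepts the highest identity wins, ties going to the
better-ranked candidate. Two presets mirror the conventional settings:
`slow` (20/500, words 12, stepwords 20) and `fast` (1/8, words 8,
stepwords 8); an `exhaustive` preset lifts the caps so every
word-sharing candidate is aligned, which is what the oracle-equivalence
tests use.

Percent identity is a declared convention, stated here precisely because
the engine and every test oracle must agree on it:

* semi-global (overlap) alignment — end gaps are free on both sequences;
* scoring: match +1, mismatch 0, gap −1 (linear);
* identity = matching columns / alignment columns, terminal gap columns
  excluded; `N` participates in alignment but never counts as a match;
* tie-breaks: the alignment endpoint is the first maximum scanning the
  bottom DP row left-to-right then the right column top-to-bottom (strict
  improvement only), and traceback prefers diagonal, then gap-in-target,
  then gap-in-query;
* the two sequences are swapped into lexicographic order before the DP.
  Optimal-score ties can otherwise make matches/columns depend on
  argument order; canonicalization makes identity exactly symmetric.

With this scoring, a gap pair (−2) is never preferred over a mismatch
column (0), so for equal-length reads differing only by substitutions the
optimal alignment is ungapped and identity is exactly the Hamming
fraction — which is what makes the synthetic benchmark's identity
arithmetic analytic.

`stepwords` is implemented as an early-termination cap on query word
scanning: k-mer collection stops after `stepwords * wordlength` query
positions. It is heuristic-only; the slow preset's cap (240 positions)
exceeds the default 150 nt read length, so it never affects
exhaustive-mode or slow-mode results at benchmark scale.

## Workflow parameters

| parameter | default | meaning |
|---|---|---|
| `s` | 0.97 | OTU identity radius |
| `subsample_fraction` (*n*) | 0.001 | fraction of failures clustered de novo to mint new centroids; at least one read whenever failures exist |
| `min_otu_size` (*c*) | 2 | filtered table keeps OTUs with total count ≥ *c*, i.e. singleton OTUs are dropped |
| `prefilter_identity` | off | permissive closed-reference screen (legacy value 0.60) discarding non-marker contaminants before clustering |
| `seed` | 1 | drives the failure subsample; a fixed seed makes the whole pipeline deterministic, independent of worker count |
| `workers` | 1 | closed-reference stages may be split; results are merge-identical to the serial run |

Notes on the defaults:

* The singleton filter keeps OTUs with total ≥ *c*. The alternative
  reading "drop totals ≤ *c*" would remove doubletons at *c* = 2,
  contradicting the intent that every kept OTU is observed at least
  twice; we use the ≥ *c* semantics (matching QIIME's `min_otu_size`).
  Both the full and the filtered table are always returned.
* The prefilter is off by default: it roughly doubles runtime for nearly
  identical downstream summaries, and contaminants are better removed
  after picking. It remains available for heavily host-contaminated data.
* Failure subsampling rounds half-up with a floor of one read, selected
  uniformly without replacement and returned in input order — this is
  what makes the `subsample_fraction = 1` limit reproduce the classic
  workflow exactly rather than up to a permutation.
* Iterative runs continue `New.*` numbering after the largest index
  already present in the reference, so expanded references never collide
  with ids minted later.

## Diversity and concordance machinery

The package evaluates whether two picking runs support the same ecology,
not which is "better". `compare_runs()` rarefies both full tables to a
common depth and reports:

* **alpha**: Pearson *r* across samples for observed OTUs and Faith's
  phylogenetic diversity. Faith's PD is the summed branch length of all
  edges on root-to-tip paths of the observed tips; the edge above the
  root, when present, participates like any edge; the empty set has PD 0.
* **beta**: Mantel *r* and *p* for unweighted UniFrac (branch length
  unique to one sample's tip set over branch length observed in either)
  and raw weighted UniFrac (`sum_e b_e |p_A(e) − p_B(e)|`; the normalized
  variant divides by the pair's maximal attainable value and is
  selectable). The Mantel test (via `vegan`) correlates strictly-upper
  -triangle entries, permutes one matrix's rows and columns jointly,
  is one-tailed for positive association (concordance is directional),
  and uses the add-one rule `p = (1 + #{perm ≥ obs}) / (1 + perms)`,
  so *p* is never zero.
* **taxa**: Pearson *r* of relative-abundance profiles at requested ranks,
  pairing vectors by (sample, taxon) over the *union* of the two runs'
  taxa with zeros for absences — the only pairing that is well defined
  when the runs produce different taxa sets. OTUs without taxonomy (all
  newly minted OTUs) pool into `Unassigned`.

OTUs present in a table but absent from the supplied tree are a hard
error — silently dropping them would corrupt both PD and UniFrac. The
synthetic generator therefore grafts every new-tier OTU onto the true
lineage tree (below) before diversity runs.

Both tables are rarefied under one seed by default, so comparing a run
against itself returns *r* = 1 everywhere; passing a different `seed_b`
isolates the rarefaction noise floor. Because near-identical tables
rarefied under a common seed make nearly common draws, the default
comparison partially cancels rarefaction noise — a paired design that
sharpens the method contrast.

## The synthetic benchmark

`make_benchmark()` produces everything the workflows and the concordance
study need with no downloads: reference centroids, novel lineages absent
from the reference, a phylogeny and taxonomy over all lineages,
multi-sample reads with ground truth, and uniform-random contaminants.

The default configuration — 60 reference lineages, 20 novel lineages,
12 samples of 2,000 reads, 2% contaminants, 150 nt reads, seed 42 —
is the package's standard study condition, sized so every end-to-end
check runs on one CPU in minutes.

Generator model, and why each choice was made:

* **Lineages** evolve from a random ancestor along a random bifurcating
  tree under independent-site Jukes–Cantor substitution, with branch
  lengths rescaled so the *closest* pair of lineages differs at the
  configured divergence (default 20%). The realized centroids are
  verified pairwise (identity ≤ 0.8, re-evolved if not), so planted
  lineages are unambiguous at the 3% OTU radius. Taxonomy strings are
  derived from internal-node paths, so related lineages share ranks.
* **Communities**: each sample draws a lineage occupancy from a
  Uniform(0.3, 0.9) gradient and lognormal(0, σ = 2) abundances over the
  occupied lineages. The occupancy gradient creates the between-sample
  taxon turnover and richness spread of real environmental surveys;
  without it all samples are statistically exchangeable and the
  concordance statistics would compare nothing but rarefaction noise.
  σ = 2 gives the heavy dominance typical of microbial abundance
  distributions.
* **Reads** are centroid copies mutated at a 0.2% per-base substitution
  rate — the residual error of quality-filtered reads. The rate must sit
  far inside the 3% OTU radius: at 0.5% the read-pair divergence tail
  already crosses the radius for abundant lineages and greedy clustering
  fragments them ("OTU splitting"), which at this benchmark's modest
  richness distorts per-sample OTU counts.
* **Contaminants** (non-marker reads, e.g. host genomic) are
  uniform-random sequences rejection-sampled until they match no
  reference centroid at ≥ 60% identity, so the legacy prefilter
  threshold separates them cleanly; their per-sample count is exact.
* **Tree coverage**: new-tier OTUs from a run are grafted onto the true
  tree as siblings of their centroid's true lineage tip (small fixed
  branch); contaminant-founded OTUs have no true location and attach at
  the root with a long branch, reflecting that they are phylogenetic
  outliers by construction.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: indels and platform-specific error
profiles (the error model is substitution-only, though the engine itself
aligns through indels), PCR chimeras (which real pipelines must remove
after picking), length variation between amplicons, taxonomy *assignment*
errors, and reference databases many orders of magnitude larger than the
query set. Runtime conclusions in particular do not transfer: at desk
scale the classic workflow is often as fast as the subsampled one.

## Numerical and degenerate-input conventions

* All randomness flows from explicit integer seeds; rerunning any
  generator, workflow or comparison with the same seed reproduces the
  result exactly, byte for byte, regardless of `workers`.
* Empty read sets yield empty results; an empty reference is an error for
  reference-based workflows.
* Samples below the rarefaction depth are dropped with a warning, not
  padded.
* Pearson *r* on a zero-variance vector is reported as `NA` with a
  warning rather than propagating `NaN`; at least 3 pairs are required.
* Counts are integers throughout; table readers reject negative or
  fractional counts.
* `round`-half-up is used for subsample sizes and contaminant counts so
  results do not depend on banker's rounding.

## Observed behavior on the standard benchmark

The test suite and `scripts/acceptance.R` recompute, at run time: the
partition identity of the `subsample_fraction = 1` limit against the
classic workflow; exact read conservation for all four workflows;
soundness of every assignment against an independent full-alignment
oracle; alpha/beta/taxa concordance of subsampled vs classic picking at
rarefaction depth 1,000 with 1,000 Mantel permutations; exact recovery of
20 planted novel lineages at zero error; the singleton filter; the
hand-derived toy values of Faith's PD (8), unweighted UniFrac (0.6) and
weighted UniFrac (2.0); Mantel type-I calibration (1,000 null trials at
200 permutations); and OTU-id stability across iterative runs. The
concordance correlations observed on the default benchmark fall in the
0.94–1.00 range. One caveat worth knowing: the *independent-seed*
rarefaction noise floor for observed OTUs is itself below 0.9 here
(~0.84), because the benchmark's contaminant singletons are pure
presence/absence noise under rarefaction — richness-based statistics on
singleton-heavy tables are noisy, which is one reason the filtered table
exists.

## Limitations

* The identity definition and candidate-ordering rules are declared
  conventions in the uclust mold, not reconstructions of any specific
  tool's internals; other implementations will draw slightly different
  OTU boundaries.
* Greedy clustering is order-dependent by construction; only the
  closed-reference stages are order- and partition-invariant.
* No reverse-complement matching (amplicons are assumed same-strand), no
  chimera detection, no FASTQ quality handling.
* The in-memory k-mer index targets benchmark-scale references (10²–10⁴
  centroids), not full production databases.
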