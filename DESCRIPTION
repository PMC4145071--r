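Package: subotu
Title: Subsampled Open-Reference OTU Picking for Marker-Gene Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Greedy centroid-based clustering of marker-gene (e.g. 16S rRNA)
    amplicon reads into operational taxonomic units (OTUs), implementing the
    de novo, closed-reference, classic open-reference and subsampled
    open-reference picking workflows, together with the alpha/beta-diversity
    and taxonomic-profile concordance statistics used to compare them and a
    synthetic benchmark generator (reference centroids, phylogeny, taxonomy
    and multi-sample reads with planted structure) so the whole evaluation
    runs without external databases. The clustering engine uses k-mer
    candidate ranking with uclust-style max_accepts/max_rejects early
    termination over semi-global pairwise alignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    phytools,
    vegan,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    phyloseq,
    optparse
Config/testthat/edition: 3
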