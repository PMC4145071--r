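# Synthetic benchmark generator: reference centroids with a known phylogeny
# and taxonomy, multi-sample reads with planted lineage structure, novel
# lineages absent from the reference, and non-marker contaminants. All
# randomness flows from the config seed.

#' Simulation configuration
#'
#' Defaults define the package's standard benchmark: 60 reference lineages
#' and 20 novel lineages (absent from the reference) on one phylogeny,
#' 12 samples of 2,000 reads with lognormal lineage abundances, 2%
#' uniform-random contaminant reads, 150 nt reads with a 0.5% per-base
#' substitution rate, and 20% expected between-lineage divergence — far
#' above the 3% within-OTU radius at s = 0.97, so planted OTUs are
#' recoverable.
#'
#' @param n_reference_lineages,n_novel_lineages Lineage counts.
#' @param contaminant_rate Fraction of each sample's reads that are
#'   uniform-random non-marker sequences.
#' @param read_length Read (and centroid) length in nt.
#' @param substitution_rate Per-base within-lineage substitution rate
#'   (residual error of quality-filtered reads). Must sit far inside the
#'   `1 - s` OTU radius: greedy clustering fragments a lineage whose
#'   read-pair divergence tail crosses the radius.
#' @param n_samples,reads_per_sample Sampling design.
#' @param lognormal_mu,lognormal_sigma Per-sample lineage abundance model;
#'   the default sigma = 2 gives the strong dominance typical of microbial
#'   abundance distributions.
#' @param occupancy Probability that a given lineage is present at all in a
#'   given sample; values below 1 create the between-sample taxon turnover
#'   seen in real environmental surveys (samples do not share all taxa).
#'   A length-2 vector `c(lo, hi)` draws each sample's occupancy uniformly
#'   from that range, emulating a richness gradient across samples (as in
#'   environmental surveys spanning, e.g., a pH gradient).
#' @param lineage_divergence Expected fraction of differing sites between
#'   the closest pair of lineage centroids.
#' @param seed Integer master seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_reference_lineages = 60L, n_novel_lineages = 20L,
                       contaminant_rate = 0.02, read_length = 150L,
                       substitution_rate = 0.002, n_samples = 12L,
                       reads_per_sample = 2000L, lognormal_mu = 0,
                       lognormal_sigma = 2, occupancy = c(0.3, 0.9),
                       lineage_divergence = 0.20, seed = 42L) {
  cfg <- list(n_reference_lineages = as.integer(n_reference_lineages),
              n_novel_lineages = as.integer(n_novel_lineages),
              contaminant_rate = contaminant_rate,
              read_length = as.integer(read_length),
              substitution_rate = substitution_rate,
              n_samples = as.integer(n_samples),
              reads_per_sample = as.integer(reads_per_sample),
              lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
              occupancy = as.numeric(occupancy),
              lineage_divergence = lineage_divergence,
              seed = as.integer(seed))
  if (cfg$n_reference_lineages < 1) stop("need at least one reference lineage")
  if (cfg$lineage_divergence <= 0 || cfg$lineage_divergence >= 0.75) {
    stop("lineage_divergence must be in (0, 0.75)")
  }
  if (!length(cfg$occupancy) %in% c(1, 2) ||
      any(cfg$occupancy <= 0) || any(cfg$occupancy > 1)) {
    stop("occupancy must be one or two probabilities in (0, 1]")
  }
  structure(cfg, class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# substitution-only mutation at a fixed per-site probability
mutate_seq <- function(seq, p) {
  if (p <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < p)
  for (i in hit) v[i] <- sample(BASES[BASES != v[i]], 1)
  paste(v, collapse = "")
}

# Jukes-Cantor: probability a site differs after d substitutions/site
jc_p_differ <- function(d) 0.75 * (1 - exp(-4 * d / 3))
jc_d_from_p <- function(p) -0.75 * log(1 - 4 * p / 3)

max_pairwise_identity <- function(seqs) {
  m <- length(seqs)
  if (m < 2) return(0)
  best <- 0
  for (i in seq_len(m - 1)) {
    mx <- max(cpp_max_identity(seqs[i], unname(seqs[(i + 1):m])))
    if (mx > best) best <- mx
  }
  best
}

#' Generate the reference set: lineage centroids, phylogeny and taxonomy
#'
#' Centroids are evolved from a random ancestor along a random bifurcating
#' tree (independent-site Jukes-Cantor substitutions), with branch lengths
#' scaled so the closest lineage pair differs at the configured divergence.
#' The realized centroids are verified: every pairwise identity must be
#' `<= 1 - lineage_divergence` (the tree is rescaled and re-evolved if
#' not). Taxonomy strings are derived from the tree's internal-node paths
#' (ranks 2-6), with the lineage id as species.
#'
#' @param config A [sim_config].
#' @return List with `reference` (named sequences of the reference
#'   lineages), `novel` (sequences of the novel lineages), `tree` (phylo
#'   over all lineages), `taxonomy` (named lineage strings for all
#'   lineages) and `lineage_class` (reference/novel per lineage).
#' @export
generate_reference_set <- function(config = sim_config()) {
  with_seed(config$seed, {
    m <- config$n_reference_lineages + config$n_novel_lineages
    labels <- c(paste0("Ref", seq_len(config$n_reference_lineages)),
                if (config$n_novel_lineages > 0)
                  paste0("Nov", seq_len(config$n_novel_lineages)))
    if (m == 1) {
      seqs <- stats::setNames(random_seq(config$read_length), labels)
      tree <- NULL
      tax <- stats::setNames(paste0("k__SimKingdom;p__CladeR;c__CladeR;o__CladeR;",
                                    "f__CladeR;g__CladeR;s__", labels), labels)
      return(list(reference = seqs[startsWith(labels, "Ref")],
                  novel = seqs[startsWith(labels, "Nov")],
                  tree = tree, taxonomy = tax,
                  lineage_class = stats::setNames(
                    ifelse(startsWith(labels, "Ref"), "reference", "novel"), labels)))
    }
    tree <- ape::rtree(m)
    tree$tip.label <- sample(labels)
    # scale so the closest pair's expected p-distance is the target divergence
    coph <- ape::cophenetic.phylo(tree)
    target_d <- jc_d_from_p(config$lineage_divergence)
    scale <- target_d / min(coph[upper.tri(coph)])
    for (try in 1:10) {
      tr <- tree
      tr$edge.length <- tree$edge.length * scale
      seqs <- evolve_along_tree(tr, config$read_length)
      if (max_pairwise_identity(seqs) <= 1 - config$lineage_divergence) break
      scale <- scale * 1.25
      if (try == 10) stop("could not reach the requested lineage divergence")
    }
    tree <- tr
    tax <- taxonomy_from_tree(tree)
    ord <- labels  # stable output order: references first
    list(reference = seqs[ord[startsWith(ord, "Ref")]],
         novel = seqs[ord[startsWith(ord, "Nov")]],
         tree = tree, taxonomy = tax[ord],
         lineage_class = stats::setNames(
           ifelse(startsWith(ord, "Ref"), "reference", "novel"), ord))
  })
}

# evolve a sequence down every edge; returns tip sequences named by label
evolve_along_tree <- function(tree, len) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  seqs <- character(ntip + nnode)
  root <- ntip + 1L
  seqs[root] <- random_seq(len)
  edges <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(edges$edge))) {
    parent <- edges$edge[e, 1]; child <- edges$edge[e, 2]
    seqs[child] <- mutate_seq(seqs[parent], jc_p_differ(edges$edge.length[e]))
  }
  stats::setNames(seqs[seq_len(ntip)], tree$tip.label)
}

# lineage strings from internal-node paths: rank 1 fixed kingdom, ranks 2-6
# from the nodes between root and tip (deepest node recycled when the path
# is short), rank 7 = the lineage id
taxonomy_from_tree <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  prefixes <- c("p__", "c__", "o__", "f__", "g__")
  tax <- vapply(seq_len(ntip), function(tip) {
    path <- ape::nodepath(tree, root, tip)
    inner <- path[-c(1, length(path))]
    ranks <- if (length(inner) == 0) rep("CladeR", 5) else {
      paste0("Clade", inner[pmin(seq_len(5), length(inner))])
    }
    paste(c("k__SimKingdom", paste0(prefixes, ranks),
            paste0("s__", tree$tip.label[tip])), collapse = ";")
  }, character(1))
  stats::setNames(tax, tree$tip.label)
}

#' Simulate demultiplexed multi-sample reads with ground truth
#'
#' Per sample, lineage abundances are drawn from a lognormal model and
#' reads are mutated copies of their lineage centroid at the within-lineage
#' substitution rate. Contaminants are uniform-random sequences verified to
#' match no reference centroid at 60% identity or better (rejection
#' sampling); their count per sample is exact
#' (`round(contaminant_rate * reads_per_sample)`). Read ids are
#' `S<k>_<serial>` so sample ids are recoverable by prefix.
#'
#' @param config A [sim_config].
#' @param ref A reference bundle from [generate_reference_set()].
#' @return List with `reads` (named sequences), `samples`
#'   (`read_id -> sample_id`), and `truth` (data.frame: read_id, lineage,
#'   category in reference/novel/contaminant).
#' @export
simulate_reads <- function(config, ref) {
  with_seed(config$seed + 1L, {
    centroids <- c(ref$reference, ref$novel)
    m <- length(centroids)
    n_cont <- as.integer(round_half_up(config$contaminant_rate * config$reads_per_sample))
    n_main <- config$reads_per_sample - n_cont
    all_reads <- character(0); all_lineage <- character(0)
    occ_rng <- range(config$occupancy)
    for (k in seq_len(config$n_samples)) {
      occ_k <- runif(1, occ_rng[1], occ_rng[2])
      w <- rlnorm(m, config$lognormal_mu, config$lognormal_sigma)
      present <- runif(m) < occ_k
      if (!any(present)) present[sample.int(m, 1)] <- TRUE
      w[!present] <- 0
      counts <- as.vector(rmultinom(1, n_main, w))
      lineage <- rep(names(centroids), counts)
      reads <- vapply(lineage, function(l) mutate_seq(centroids[[l]],
                                                      config$substitution_rate),
                      character(1), USE.NAMES = FALSE)
      if (n_cont > 0) {
        cont <- character(n_cont)
        for (j in seq_len(n_cont)) {
          repeat {
            cand <- random_seq(config$read_length)
            if (max(cpp_max_identity(cand, unname(ref$reference))) < 0.60) break
          }
          cont[j] <- cand
        }
        reads <- c(reads, cont)
        lineage <- c(lineage, paste0("contam_S", k, "_", seq_len(n_cont)))
      }
      ord <- sample(length(reads))
      reads <- reads[ord]; lineage <- lineage[ord]
      names(reads) <- paste0("S", k, "_", seq_along(reads))
      all_reads <- c(all_reads, reads)
      all_lineage <- c(all_lineage, lineage)
    }
    category <- ifelse(startsWith(all_lineage, "Ref"), "reference",
                       ifelse(startsWith(all_lineage, "Nov"), "novel",
                              "contaminant"))
    list(reads = all_reads,
         samples = sample_assignment(names(all_reads)),
         truth = data.frame(read_id = names(all_reads),
                            lineage = all_lineage, category = category,
                            stringsAsFactors = FALSE))
  })
}

#' Graft a run's new OTUs onto the true lineage tree
#'
#' Every new-tier OTU (tiers `new_reference` and `cleanup`) of a finished
#' run is added as a tip: OTUs whose centroid read derives from a planted
#' lineage are grafted as a sibling of that lineage's tip with a small
#' fixed branch length; OTUs founded by contaminant reads have no true
#' location and are attached at the root with a long branch (they are
#' phylogenetic outliers by construction). Afterwards every OTU id of the
#' run's table resolves as a tip.
#'
#' @param tree The true lineage phylogeny.
#' @param result An `otu_result`.
#' @param truth The ground-truth data.frame from [simulate_reads()].
#' @param graft_branch Branch length for lineage-derived grafts.
#' @param contaminant_branch Branch length for contaminant grafts.
#' @return The extended `phylo` tree.
#' @export
extend_tree_with_new_otus <- function(tree, result, truth,
                                      graft_branch = 0.01,
                                      contaminant_branch = 0.5) {
  tiers <- result$otu_map$tiers
  new_ids <- names(tiers)[tiers != "reference"]
  if (length(new_ids) == 0) return(tree)
  cents <- result$otu_map$centroids[new_ids]
  idx <- match(cents, truth$read_id)
  if (anyNA(idx)) stop("centroid read missing from ground truth: ",
                       cents[which(is.na(idx))[1]])
  for (z in seq_along(new_ids)) {
    lin <- truth$lineage[idx[z]]
    if (truth$category[idx[z]] == "contaminant") {
      tree <- phytools::bind.tip(tree, new_ids[z],
                                 edge.length = contaminant_branch,
                                 where = length(tree$tip.label) + 1L,
                                 position = 0)
    } else {
      tipw <- which(tree$tip.label == lin)
      el <- tree$edge.length[tree$edge[, 2] == tipw]
      tree <- phytools::bind.tip(tree, new_ids[z], edge.length = graft_branch,
                                 where = tipw,
                                 position = min(graft_branch, el / 2))
    }
  }
  tree
}

#' Generate the complete benchmark bundle
#'
#' One call produces everything the workflows and the concordance study
#' need: reads, reference centroids, the true phylogeny, taxonomy and the
#' ground-truth read-to-lineage table. When `output_dir` is given the
#' bundle is also written to disk (`reads.fna`, `reference.fna`,
#' `tree_true.nwk`, `taxonomy.tsv`, `truth.tsv`). Identical seeds produce
#' identical bundles.
#'
#' @param config A [sim_config].
#' @param output_dir Optional directory to write the bundle into.
#' @return List with `reads`, `samples`, `reference`, `novel`, `tree`,
#'   `taxonomy`, `truth` and `config`.
#' @export
make_benchmark <- function(config = sim_config(), output_dir = NULL) {
  ref <- generate_reference_set(config)
  sim <- simulate_reads(config, ref)
  bundle <- list(reads = sim$reads, samples = sim$samples,
                 reference = ref$reference, novel = ref$novel,
                 tree = ref$tree, taxonomy = ref$taxonomy,
                 truth = sim$truth, config = config)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(bundle$reads, file.path(output_dir, "reads.fna"))
    write_fasta(bundle$reference, file.path(output_dir, "reference.fna"))
    if (!is.null(bundle$tree)) {
      ape::write.tree(bundle$tree, file.path(output_dir, "tree_true.nwk"))
    }
    write_taxonomy(bundle$taxonomy, file.path(output_dir, "taxonomy.tsv"))
    write.table(bundle$truth, file.path(output_dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  bundle
}
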