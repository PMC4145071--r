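# Alpha and beta diversity over a rooted phylogeny (ape "phylo" trees).
#
# All metrics here are computed by a single post-order accumulation: each
# edge is weighted by the total count (or presence) of the tips descending
# from it. The edge above the root (tree$root.edge), when present,
# participates like any other edge; every tip descends from it.

# Per-edge totals of a named tip weight vector: returns the weight sum under
# the child node of each edge (in tree$edge order).
edge_totals <- function(tree, w) {
  ntip <- length(tree$tip.label)
  val <- numeric(ntip + tree$Nnode)
  idx <- match(names(w), tree$tip.label)
  val[idx] <- w
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    val[tr$edge[e, 1]] <- val[tr$edge[e, 1]] + val[tr$edge[e, 2]]
  }
  # report in the original tree's edge order
  val[tree$edge[, 2]]
}

check_tips <- function(tree, ids) {
  unknown <- setdiff(ids, tree$tip.label)
  if (length(unknown) > 0) {
    stop("OTU id(s) missing from the tree: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
}

#' Number of OTUs observed in a sample
#'
#' @param counts Numeric vector of per-OTU counts for one sample.
#' @return Integer count of OTUs with count > 0.
#' @export
observed_otus <- function(counts) sum(counts > 0)

#' Faith's phylogenetic diversity
#'
#' Total branch length of all edges on the paths from the root to each
#' present tip, each edge counted once. The empty set has PD 0.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param present_otus Character vector of present tip labels (must all be
#'   tips of the tree).
#' @return Branch-length sum.
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:2):3,C:4):0;")
#' faith_pd(tree, c("A", "C"))  # 1 + 3 + 4 = 8
#' @export
faith_pd <- function(tree, present_otus) {
  present_otus <- unique(as.character(present_otus))
  if (length(present_otus) == 0) return(0)
  check_tips(tree, present_otus)
  w <- stats::setNames(rep(1, length(present_otus)), present_otus)
  tot <- edge_totals(tree, w)
  pd <- sum(tree$edge.length[tot > 0])
  if (!is.null(tree$root.edge)) pd <- pd + tree$root.edge
  pd
}

#' Unweighted UniFrac distance between two samples
#'
#' Branch length unique to one sample's observed tip set divided by branch
#' length observed in either; presence/absence only. Identical presence
#' sets give 0, phylogenetically disjoint ones give 1.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param a,b Named per-OTU count vectors (names must be tips).
#' @return Distance in `[0, 1]`.
#' @export
unweighted_unifrac <- function(tree, a, b) {
  check_tips(tree, c(names(a), names(b)))
  in_a <- edge_totals(tree, a[a > 0]) > 0
  in_b <- edge_totals(tree, b[b > 0]) > 0
  either <- in_a | in_b
  denom <- sum(tree$edge.length[either])
  if (!is.null(tree$root.edge) && any(either)) {
    # the root edge is shared whenever both samples are non-empty
    denom <- denom + tree$root.edge
    if (xor(any(in_a), any(in_b))) {
      return((sum(tree$edge.length[xor(in_a, in_b)]) + tree$root.edge) / denom)
    }
  }
  if (denom == 0) return(0)
  sum(tree$edge.length[xor(in_a, in_b)]) / denom
}

#' Weighted UniFrac distance between two samples
#'
#' `sum_e b_e * |pA(e) - pB(e)|` where `pX(e)` is the proportion of sample
#' X's reads descending from edge `e`. The normalized variant divides by the
#' maximal attainable value for the pair,
#' `sum_tips d_j * (pA_j + pB_j)` with `d_j` the root-to-tip distance.
#'
#' @inheritParams unweighted_unifrac
#' @param normalized Divide by the pair's maximal attainable value.
#' @return Non-negative distance (in `[0, 1]` when normalized).
#' @export
weighted_unifrac <- function(tree, a, b, normalized = FALSE) {
  check_tips(tree, c(names(a), names(b)))
  ta <- sum(a); tb <- sum(b)
  if (ta <= 0 || tb <= 0) stop("both samples must have positive totals")
  pa <- edge_totals(tree, a) / ta
  pb <- edge_totals(tree, b) / tb
  raw <- sum(tree$edge.length * abs(pa - pb))
  # root edge: both proportions are 1, contributing 0
  if (!normalized) return(raw)
  depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (!is.null(tree$root.edge)) depth <- depth + tree$root.edge
  pa_tip <- stats::setNames(numeric(length(tree$tip.label)), tree$tip.label)
  pb_tip <- pa_tip
  pa_tip[names(a)] <- a / ta
  pb_tip[names(b)] <- b / tb
  denom <- sum(depth * (pa_tip + pb_tip))
  if (denom == 0) return(0)
  raw / denom
}

#' Pairwise beta-diversity matrix for all samples of an OTU table
#'
#' @param table An [otu_table]; every OTU id must be a tip of `tree`.
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param metric One of `"unweighted_unifrac"`, `"weighted_unifrac"`,
#'   `"weighted_normalized_unifrac"`.
#' @return Symmetric distance matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
beta_diversity_matrix <- function(table, tree,
                                  metric = c("unweighted_unifrac",
                                             "weighted_unifrac",
                                             "weighted_normalized_unifrac")) {
  metric <- match.arg(metric)
  check_tips(tree, rownames(table))
  ids <- colnames(table)
  n <- length(ids)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(dm)
  cols <- lapply(ids, function(s) stats::setNames(unclass(table)[, s], rownames(table)))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      d <- switch(metric,
        unweighted_unifrac = unweighted_unifrac(tree, cols[[i]], cols[[j]]),
        weighted_unifrac = weighted_unifrac(tree, cols[[i]], cols[[j]]),
        weighted_normalized_unifrac =
          weighted_unifrac(tree, cols[[i]], cols[[j]], normalized = TRUE))
      dm[i, j] <- dm[j, i] <- d
    }
  }
  dm
}
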