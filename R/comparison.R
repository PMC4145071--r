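#' Pearson product-moment correlation with an explicit undefined case
#'
#' @param x,y Paired numeric vectors (at least 3 pairs).
#' @return The correlation coefficient, or `NA` (with a warning) when either
#'   vector has zero variance, where the statistic is undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance: Pearson r undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Mantel test between two sample distance matrices
#'
#' The statistic is the Pearson correlation over the strictly-upper-triangle
#' entries; significance comes from jointly permuting rows and columns of
#' the second matrix (`vegan::mantel`), one-tailed for positive association,
#' with the add-one rule `p = (1 + #\{permuted r >= observed r\}) /
#' (1 + permutations)` so p is never 0.
#'
#' @param dmA,dmB Symmetric distance matrices over the same sample ids in
#'   the same order (n >= 3).
#' @param permutations Number of Monte Carlo permutations (default 1000).
#' @param seed Integer RNG seed.
#' @return List with elements `r` and `p`.
#' @export
mantel_test <- function(dmA, dmB, permutations = 1000L, seed = 1L) {
  if (is.null(rownames(dmA)) || is.null(rownames(dmB)) ||
      !identical(rownames(dmA), rownames(dmB))) {
    stop("distance matrices must share identical sample ids in the same order")
  }
  if (nrow(dmA) < 3) stop("need at least 3 samples")
  fit <- with_seed(seed,
    vegan::mantel(stats::as.dist(dmA), stats::as.dist(dmB),
                  method = "pearson", permutations = permutations))
  list(r = unname(fit$statistic), p = unname(fit$signif))
}

#' Concordance statistics between two OTU picking runs
#'
#' Both runs' full tables are rarefied to a common depth, then compared on
#' the samples they share: Pearson r of per-sample alpha diversity
#' (observed OTUs and Faith's PD), Mantel r/p of weighted and unweighted
#' UniFrac distance matrices, and Pearson r of taxonomic profiles at each
#' requested rank. Taxa vectors are paired by (sample, taxon) over the
#' union of the two runs' taxa, absent taxa filled with 0 — the only
#' pairing that is well-defined when the runs yield different taxa sets.
#'
#' @param resultA,resultB `otu_result` objects.
#' @param treeA,treeB Trees covering every OTU id of the respective tables
#'   (see [extend_tree_with_new_otus()]).
#' @param depth Rarefaction depth.
#' @param seed Integer RNG seed (drives both rarefactions and the Mantel
#'   permutations); comparing a result against itself under one seed gives
#'   r = 1 everywhere.
#' @param seed_b Rarefaction seed for the second table (defaults to `seed`);
#'   set it differently to isolate the rarefaction noise floor.
#' @param permutations Mantel permutations.
#' @param levels Taxonomic ranks for the profile correlations.
#' @return A `concordance_report`: lists `alpha` (r per metric), `beta`
#'   (r and p per UniFrac variant), `taxa` (r per rank), plus metadata.
#' @export
compare_runs <- function(resultA, resultB, treeA, treeB, depth,
                         seed = 1L, seed_b = seed, permutations = 1000L,
                         levels = c(2L, 6L)) {
  tabA <- rarefy_table(resultA$table_full, depth, seed = seed)
  tabB <- rarefy_table(resultB$table_full, depth, seed = seed_b)
  shared <- intersect(colnames(tabA), colnames(tabB))
  if (length(shared) < 3) stop("need at least 3 shared samples after rarefaction")
  tabA <- otu_table(unclass(tabA)[, shared, drop = FALSE], attr(tabA, "taxonomy"))
  tabB <- otu_table(unclass(tabB)[, shared, drop = FALSE], attr(tabB, "taxonomy"))

  alpha <- list(
    observed_otus = pearson_r(apply(tabA, 2, observed_otus),
                              apply(tabB, 2, observed_otus)),
    faith_pd = pearson_r(
      vapply(shared, function(s) faith_pd(treeA, rownames(tabA)[unclass(tabA)[, s] > 0]), numeric(1)),
      vapply(shared, function(s) faith_pd(treeB, rownames(tabB)[unclass(tabB)[, s] > 0]), numeric(1))))

  beta <- list()
  for (metric in c("unweighted_unifrac", "weighted_unifrac")) {
    dmA <- beta_diversity_matrix(tabA, treeA, metric)
    dmB <- beta_diversity_matrix(tabB, treeB, metric)
    beta[[metric]] <- mantel_test(dmA, dmB, permutations = permutations,
                                  seed = seed + 2L)
  }

  taxa <- list()
  for (lev in levels) {
    profA <- collapse_taxonomy(tabA, lev)
    profB <- collapse_taxonomy(tabB, lev)
    union_taxa <- union(rownames(profA), rownames(profB))
    fill <- function(p) {
      m <- matrix(0, length(union_taxa), length(shared),
                  dimnames = list(union_taxa, shared))
      m[rownames(p), ] <- p[, shared]
      m
    }
    taxa[[paste0("rank", lev)]] <- pearson_r(as.vector(fill(profA)),
                                             as.vector(fill(profB)))
  }

  structure(list(alpha = alpha, beta = beta, taxa = taxa,
                 depth = depth, seed = seed, permutations = permutations,
                 samples = shared),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance report (", length(x$samples), " samples, depth ",
      x$depth, ")\n", sep = "")
  cat("alpha diversity Pearson r:\n")
  for (m in names(x$alpha)) cat(sprintf("  %-22s %.4f\n", m, x$alpha[[m]]))
  cat("beta diversity Mantel (", x$permutations, " permutations):\n", sep = "")
  for (m in names(x$beta)) {
    cat(sprintf("  %-22s r = %.4f, p = %.4g\n", m, x$beta[[m]]$r, x$beta[[m]]$p))
  }
  cat("taxonomic profile Pearson r:\n")
  for (m in names(x$taxa)) cat(sprintf("  %-22s %.4f\n", m, x$taxa[[m]]))
  invisible(x)
}
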