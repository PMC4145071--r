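#' Build an OTU-by-sample count table from an OTU map
#'
#' @param map An [otu_map].
#' @param samples Named character vector `read_id -> sample_id` covering
#'   every read in the map (see [sample_assignment()]).
#' @param taxonomy Optional named character vector of lineages to attach.
#' @return An [otu_table]; `counts[o, s]` is the number of reads of sample
#'   `s` in OTU `o`, so the grand total equals the number of mapped reads.
#' @export
build_table <- function(map, samples, taxonomy = NULL) {
  otus <- if (inherits(map, "otu_map")) map$otus else map
  all_reads <- unlist(otus, use.names = FALSE)
  if (length(all_reads) == 0) {
    return(otu_table(matrix(0L, 0, 0, dimnames = list(character(), character())),
                     taxonomy = taxonomy))
  }
  missing <- setdiff(all_reads, names(samples))
  if (length(missing) > 0) stop("no sample assignment for read: ", missing[1])
  sample_ids <- sort(unique(unname(samples[all_reads])))
  counts <- matrix(0L, nrow = length(otus), ncol = length(sample_ids),
                   dimnames = list(names(otus), sample_ids))
  for (i in seq_along(otus)) {
    tab <- table(samples[otus[[i]]])
    counts[i, names(tab)] <- as.integer(tab)
  }
  otu_table(counts, taxonomy = taxonomy)
}

#' Rarefy an OTU table to even sampling depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads;
#' samples whose total is below `depth` are dropped with a warning.
#' Deterministic for a fixed seed.
#'
#' @param table An [otu_table].
#' @param depth Target depth (>= 1).
#' @param seed Integer RNG seed.
#' @return The rarefied [otu_table].
#' @export
rarefy_table <- function(table, depth, seed = 1L) {
  if (depth < 1) stop("depth must be >= 1")
  totals <- colSums(table)
  keep <- totals >= depth
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(colnames(table)[!keep], collapse = ", "))
  }
  kept <- colnames(table)[keep]
  out <- matrix(0L, nrow = nrow(table), ncol = length(kept),
                dimnames = list(rownames(table), kept))
  with_seed(seed, {
    for (s in kept) {
      pool <- rep.int(seq_len(nrow(table)), unclass(table)[, s])
      pick <- sample(pool, depth)
      tab <- tabulate(pick, nbins = nrow(table))
      out[, s] <- as.integer(tab)
    }
  })
  otu_table(out, taxonomy = attr(table, "taxonomy"))
}

# Lineage prefix at a given rank depth. Ranks are indexed 1 = kingdom ...
# 7 = species; "k__"-style prefixes are tolerated but not required.
lineage_prefix <- function(lineage, level) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  vapply(parts, function(p) {
    p <- trimws(p)
    paste(p[seq_len(min(level, length(p)))], collapse = ";")
  }, character(1))
}

#' Collapse an OTU table to relative abundances at a taxonomic rank
#'
#' Rows of the result are the distinct lineage prefixes of the requested
#' depth; OTUs without a taxonomy entry are pooled into `"Unassigned"`.
#' Per-sample values sum to 1 whenever the sample total is positive.
#'
#' @param table An [otu_table] with (possibly partial) taxonomy.
#' @param level Rank depth, 1 = kingdom ... 7 = species.
#' @return Numeric matrix (taxon x sample) of relative abundances.
#' @export
collapse_taxonomy <- function(table, level) {
  tax <- attr(table, "taxonomy")
  lin <- rep("Unassigned", nrow(table))
  names(lin) <- rownames(table)
  if (!is.null(tax)) {
    known <- intersect(rownames(table), names(tax))
    lin[known] <- lineage_prefix(tax[known], level)
  }
  groups <- factor(lin, levels = unique(lin))
  collapsed <- rowsum(unclass(table) + 0, groups)
  totals <- colSums(collapsed)
  rel <- sweep(collapsed, 2, ifelse(totals > 0, totals, 1), "/")
  rownames(rel) <- levels(groups)
  rel
}

#' Merge OTU tables, summing overlapping cells
#'
#' The result holds the union of OTU and sample ids; counts present in
#' several tables are added.
#'
#' @param tables A list of [otu_table] objects.
#' @return The merged [otu_table].
#' @export
merge_tables <- function(tables) {
  stopifnot(is.list(tables), length(tables) > 0)
  otu_ids <- unique(unlist(lapply(tables, rownames)))
  sample_ids <- unique(unlist(lapply(tables, colnames)))
  out <- matrix(0L, nrow = length(otu_ids), ncol = length(sample_ids),
                dimnames = list(otu_ids, sample_ids))
  tax <- character()
  for (t in tables) {
    if (nrow(t) > 0 && ncol(t) > 0) {
      out[rownames(t), colnames(t)] <- out[rownames(t), colnames(t)] + unclass(t)
    }
    tt <- attr(t, "taxonomy")
    if (!is.null(tt)) tax <- c(tax, tt[setdiff(names(tt), names(tax))])
  }
  otu_table(out, taxonomy = if (length(tax) > 0) tax)
}

#' Attach a taxonomy map to an OTU table
#'
#' OTUs without an entry (e.g. newly minted `New.*` OTUs) simply stay
#' unannotated and collapse into `"Unassigned"` downstream.
#'
#' @param table An [otu_table].
#' @param taxonomy Named character vector `otu_id -> lineage`.
#' @return The table with taxonomy attached.
#' @export
set_taxonomy <- function(table, taxonomy) {
  otu_table(unclass(table), taxonomy = taxonomy)
}
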