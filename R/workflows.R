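#' Workflow parameters
#'
#' Bundles the clustering knobs with the workflow-level settings: the
#' failure subsample fraction `n` (default 0.001, i.e. 0.1%), the minimum
#' OTU size `c` for the filtered table (default 2, so singleton OTUs are
#' excluded), the optional permissive prefilter identity (disabled by
#' default; the legacy screening value is 0.60), the RNG seed and the
#' worker count for closed-reference stages.
#'
#' @param clustering A [clustering_params].
#' @param subsample_fraction Fraction of closed-reference failures clustered
#'   de novo to mint new reference centroids, in `[0, 1]`.
#' @param min_otu_size Minimum total count for an OTU to be kept in the
#'   filtered table.
#' @param prefilter_identity Identity threshold for the contaminant
#'   prefilter, or `NULL` (disabled).
#' @param seed Integer seed; a fixed seed makes the whole pipeline
#'   deterministic.
#' @param workers Worker count for closed-reference stages.
#' @return An object of class `workflow_params`.
#' @export
workflow_params <- function(clustering = clustering_params(),
                            subsample_fraction = 0.001,
                            min_otu_size = 2L,
                            prefilter_identity = NULL,
                            seed = 1L,
                            workers = 1L) {
  if (!(subsample_fraction >= 0 && subsample_fraction <= 1)) {
    stop("subsample_fraction must be in [0, 1]")
  }
  if (min_otu_size < 0) stop("min_otu_size must be >= 0")
  if (!is.null(prefilter_identity)) {
    if (!(prefilter_identity >= 0 && prefilter_identity <= 1)) {
      stop("prefilter_identity must be in [0, 1]")
    }
    if (prefilter_identity > clustering$s) {
      stop("prefilter_identity must not exceed the clustering threshold s")
    }
  }
  structure(list(clustering = clustering,
                 subsample_fraction = subsample_fraction,
                 min_otu_size = as.integer(min_otu_size),
                 prefilter_identity = prefilter_identity,
                 seed = as.integer(seed),
                 workers = as.integer(workers)),
            class = "workflow_params")
}

#' Prefilter reads against a reference at a permissive identity
#'
#' Reads with no reference match at the given identity are discarded; the
#' goal is removing non-marker contaminants (e.g. host genomic sequence)
#' before clustering. Runs through [assign_closed_reference()], so it is
#' partition-invariant.
#'
#' @inheritParams assign_closed_reference
#' @param identity Screening threshold (legacy default 0.60).
#' @return List with `kept` and `discarded` named sequence vectors.
#' @export
prefilter_reads <- function(reads, reference, identity = 0.60,
                            params = clustering_params(), workers = 1L) {
  if (identity > params$s) stop("prefilter identity must be <= s")
  if (identity <= 0) return(list(kept = reads, discarded = reads[0]))
  p <- params
  p$s <- identity
  res <- assign_closed_reference(reads, reference, p, workers = workers)
  kept_ids <- res$assignments$read_id
  list(kept = reads[names(reads) %in% kept_ids],
       discarded = reads[names(reads) %in% res$failures])
}

#' Randomly subsample closed-reference failures
#'
#' Draws `round(length(failures) * fraction)` reads (round-half-up, floor of
#' 1 whenever there are failures and `fraction > 0`) uniformly without
#' replacement. The selected reads are returned in their original input
#' order, so `fraction = 1` reproduces the input exactly.
#'
#' @param failures Character vector of read ids (or named sequences).
#' @param fraction Subsample fraction in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return List with `subsample` and `remainder`, disjoint, union = input.
#' @export
subsample_failures <- function(failures, fraction, seed = 1L) {
  if (!(fraction >= 0 && fraction <= 1)) stop("fraction must be in [0, 1]")
  n <- length(failures)
  if (n == 0 || fraction == 0) {
    return(list(subsample = failures[0], remainder = failures))
  }
  k <- max(1L, as.integer(round_half_up(n * fraction)))
  k <- min(k, n)
  pick <- with_seed(seed, sort(sample.int(n, k)))
  list(subsample = failures[pick],
       remainder = if (k == n) failures[0] else failures[-pick])
}

# Shared plumbing: build an OtuResult from a finished map.
finish_result <- function(map, reads_all, sample_map, params,
                          new_centroid_seqs, prefilter_discards, unmatched) {
  samples <- sample_assignment(unlist(map$otus, use.names = FALSE), sample_map)
  table_full <- build_table(map, samples)
  structure(list(
    otu_map = map,
    table_full = table_full,
    table_filtered = filter_min_count(table_full, params$min_otu_size),
    new_centroids = new_centroid_seqs,
    prefilter_discards = prefilter_discards,
    unmatched = unmatched,
    params = params), class = "otu_result")
}

#' @export
print.otu_result <- function(x, ...) {
  cat("otu_result:", nrow(x$table_full), "OTUs,",
      sum(x$table_full), "reads in table,",
      length(x$prefilter_discards), "prefilter discards,",
      length(x$unmatched), "unmatched\n")
  if (!is.null(x$otu_map$tiers)) print(table(x$otu_map$tiers))
  invisible(x)
}

maybe_prefilter <- function(reads, reference, params) {
  if (is.null(params$prefilter_identity)) {
    return(list(kept = reads, discarded = reads[0]))
  }
  prefilter_reads(reads, reference, identity = params$prefilter_identity,
                  params = params$clustering, workers = params$workers)
}

#' Closed-reference OTU picking workflow
#'
#' Reads are assigned to reference centroids at identity `>= s`; reads that
#' fail to match any centroid are excluded from the table and recorded in
#' `unmatched`. OTU ids are reference centroid ids; no new centroids are
#' minted.
#'
#' @param reads,reference Named character vectors of sequences.
#' @param params A [workflow_params].
#' @param sample_map Optional explicit `read_id -> sample_id` map;
#'   otherwise sample ids are inferred from read-id prefixes.
#' @return An `otu_result`.
#' @export
pick_closed_reference <- function(reads, reference, params = workflow_params(),
                                  sample_map = NULL) {
  pf <- maybe_prefilter(reads, reference, params)
  res <- assign_closed_reference(pf$kept, reference, params$clustering,
                                 workers = params$workers)
  otus <- split(res$assignments$read_id, factor(res$assignments$otu_id,
                                                levels = unique(res$assignments$otu_id)))
  map <- otu_map(as.list(otus),
                 centroids = stats::setNames(names(otus), names(otus)),
                 tiers = stats::setNames(rep("reference", length(otus)), names(otus)))
  finish_result(map, reads, sample_map, params,
                new_centroid_seqs = reads[0],
                prefilter_discards = names(pf$discarded),
                unmatched = res$failures)
}

#' De novo OTU picking workflow
#'
#' All reads are clustered greedily against centroids defined from the reads
#' themselves; no reference is used.
#'
#' @inheritParams pick_closed_reference
#' @return An `otu_result`.
#' @export
pick_de_novo <- function(reads, params = workflow_params(), sample_map = NULL) {
  map <- cluster_de_novo(reads, params$clustering, otu_prefix = "denovo",
                         tier = "new_reference")
  finish_result(map, reads, sample_map, params,
                new_centroid_seqs = reads[map$centroids],
                prefilter_discards = character(),
                unmatched = character())
}

#' Classic open-reference OTU picking workflow
#'
#' A closed-reference pass against the reference, then a single serial
#' de novo pass over *all* failures.
#'
#' @inheritParams pick_closed_reference
#' @return An `otu_result` with `reference` and `new_reference` tiers.
#' @export
pick_classic_open_reference <- function(reads, reference,
                                        params = workflow_params(),
                                        sample_map = NULL) {
  pf <- maybe_prefilter(reads, reference, params)
  closed <- assign_closed_reference(pf$kept, reference, params$clustering,
                                    workers = params$workers)
  ref_otus <- split(closed$assignments$read_id,
                    factor(closed$assignments$otu_id,
                           levels = unique(closed$assignments$otu_id)))
  start <- next_new_otu_index(names(reference), "New.ReferenceOTU")
  dn <- cluster_de_novo(pf$kept[closed$failures], params$clustering,
                        otu_prefix = "New.ReferenceOTU", start_index = start,
                        tier = "new_reference")
  map <- otu_map(
    c(as.list(ref_otus), dn$otus),
    centroids = c(stats::setNames(names(ref_otus), names(ref_otus)), dn$centroids),
    tiers = c(stats::setNames(rep("reference", length(ref_otus)), names(ref_otus)),
              dn$tiers))
  finish_result(map, reads, sample_map, params,
                new_centroid_seqs = pf$kept[dn$centroids],
                prefilter_discards = names(pf$discarded),
                unmatched = character())
}

# First free index for a New.* OTU id family, scanning existing ids so that
# iterative runs never reuse an id.
next_new_otu_index <- function(existing_ids, prefix) {
  hits <- grep(paste0("^", gsub("\\.", "\\\\.", prefix), "[0-9]+$"),
               existing_ids, value = TRUE)
  if (length(hits) == 0) return(0L)
  max(as.integer(sub(paste0("^", gsub("\\.", "\\\\.", prefix)), "", hits))) + 1L
}

#' Subsampled open-reference OTU picking workflow
#'
#' The five-stage protocol: (1) parallel closed-reference assignment against
#' the reference at identity `s`; (2) a random subsample of fraction `n` of
#' the failures is clustered de novo, its centroids minting the
#' `New.ReferenceOTU<i>` tier; (3) the remaining failures are clustered
#' closed-reference against those new centroids; (4) reads still unassigned
#' are clustered de novo into the `New.CleanUpReferenceOTU<i>` tier;
#' (5) the three tiers are merged into one table, emitted both in full and
#' filtered at the minimum OTU size `c`.
#'
#' @inheritParams pick_closed_reference
#' @return An `otu_result` with all three tiers, the new-tier centroid
#'   sequences, and both tables.
#' @export
pick_subsampled_open_reference <- function(reads, reference,
                                           params = workflow_params(),
                                           sample_map = NULL) {
  assert_seqs(reference, "reference")
  if (length(reference) == 0) stop("reference must be non-empty")
  pf <- maybe_prefilter(reads, reference, params)
  closed <- assign_closed_reference(pf$kept, reference, params$clustering,
                                    workers = params$workers)
  ref_otus <- split(closed$assignments$read_id,
                    factor(closed$assignments$otu_id,
                           levels = unique(closed$assignments$otu_id)))

  sub <- subsample_failures(closed$failures, params$subsample_fraction,
                            seed = params$seed)
  nr_start <- next_new_otu_index(names(reference), "New.ReferenceOTU")
  new_ref <- cluster_de_novo(pf$kept[sub$subsample], params$clustering,
                             otu_prefix = "New.ReferenceOTU",
                             start_index = nr_start, tier = "new_reference")
  new_ref_seqs <- pf$kept[new_ref$centroids]

  cleanup_input <- sub$remainder
  if (length(new_ref_seqs) > 0 && length(sub$remainder) > 0) {
    stage2 <- assign_closed_reference(pf$kept[sub$remainder], new_ref_seqs,
                                      params$clustering, workers = params$workers)
    if (nrow(stage2$assignments) > 0) {
      extra <- split(stage2$assignments$read_id,
                     stage2$assignments$otu_id)
      for (oid in names(extra)) {
        nr_oid <- names(new_ref$centroids)[match(oid, new_ref$centroids)]
        new_ref$otus[[nr_oid]] <- c(new_ref$otus[[nr_oid]], extra[[oid]])
      }
    }
    cleanup_input <- stage2$failures
  }

  cu_start <- next_new_otu_index(names(reference), "New.CleanUpReferenceOTU")
  cleanup <- cluster_de_novo(pf$kept[cleanup_input], params$clustering,
                             otu_prefix = "New.CleanUpReferenceOTU",
                             start_index = cu_start, tier = "cleanup")

  map <- otu_map(
    c(as.list(ref_otus), new_ref$otus, cleanup$otus),
    centroids = c(stats::setNames(names(ref_otus), names(ref_otus)),
                  new_ref$centroids, cleanup$centroids),
    tiers = c(stats::setNames(rep("reference", length(ref_otus)), names(ref_otus)),
              new_ref$tiers, cleanup$tiers))
  finish_result(map, reads, sample_map, params,
                new_centroid_seqs = pf$kept[c(new_ref$centroids, cleanup$centroids)],
                prefilter_discards = names(pf$discarded),
                unmatched = character())
}

#' Drop OTUs below a minimum total count
#'
#' Keeps OTUs whose total count across samples is `>= c`; kept counts are
#' never modified. With the default `c = 2` every kept OTU is observed at
#' least twice, i.e. singleton OTUs are excluded.
#'
#' @param table An [otu_table].
#' @param c Minimum total count.
#' @return The filtered [otu_table].
#' @export
filter_min_count <- function(table, c = 2L) {
  keep <- rowSums(table) >= c
  tax <- attr(table, "taxonomy")
  out <- unclass(table)[keep, , drop = FALSE]
  otu_table(out, taxonomy = if (!is.null(tax)) tax[intersect(names(tax), rownames(out))])
}

#' Fold a run's new centroids into the reference for future runs
#'
#' Appends the new-tier centroid sequences of a finished run to the
#' reference collection under their `New.*` OTU ids, so a later run assigns
#' matching reads to the *same* OTU ids through its closed-reference tier
#' (iterative picking with stable OTU definitions across runs).
#'
#' @param reference Named character vector of reference centroids.
#' @param result An `otu_result`.
#' @return The expanded reference collection.
#' @export
iterative_update_reference <- function(reference, result) {
  newc <- result$new_centroids
  if (length(newc) == 0) return(reference)
  ids <- names(result$otu_map$centroids)[match(names(newc), result$otu_map$centroids)]
  add <- stats::setNames(unname(newc), ids)
  assert_seqs(c(reference, add), "expanded reference")
  c(reference, add)
}
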