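#' Clustering parameters (uclust-style heuristic knobs)
#'
#' `s` is the percent-identity threshold defining an OTU (default 0.97).
#' `max_accepts` / `max_rejects` bound how many candidate centroids are
#' evaluated per query before giving up; `wordlength` is the k-mer size used
#' to rank candidates and `stepwords` caps how much of the query is scanned
#' for k-mers (scanning stops after `stepwords * wordlength` query
#' positions). The `"slow"` preset (20/500/20/12) matches the conservative
#' settings historically used to build reference OTU collections; `"fast"`
#' (1/8/8/8) matches uclust's defaults and trades occasional suboptimal
#' assignments for speed. `"exhaustive"` lifts both caps so every candidate
#' sharing a word is aligned (useful for oracle comparisons).
#'
#' @param s Identity threshold in (0, 1].
#' @param max_accepts,max_rejects,wordlength,stepwords Positive integers;
#'   defaults come from `preset`.
#' @param preset `"slow"`, `"fast"` or `"exhaustive"`.
#' @return An object of class `clustering_params`.
#' @examples
#' clustering_params(preset = "fast")
#' @export
clustering_params <- function(s = 0.97, preset = c("slow", "fast", "exhaustive"),
                              max_accepts = NULL, max_rejects = NULL,
                              wordlength = NULL, stepwords = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    slow       = list(max_accepts = 20L, max_rejects = 500L, stepwords = 20L, wordlength = 12L),
    fast       = list(max_accepts = 1L,  max_rejects = 8L,   stepwords = 8L,  wordlength = 8L),
    exhaustive = list(max_accepts = .Machine$integer.max, max_rejects = .Machine$integer.max,
                      stepwords = .Machine$integer.max %/% 16L, wordlength = 12L))
  p <- list(
    s = s,
    max_accepts = as.integer(max_accepts %||% def$max_accepts),
    max_rejects = as.integer(max_rejects %||% def$max_rejects),
    wordlength = as.integer(wordlength %||% def$wordlength),
    stepwords = as.integer(stepwords %||% def$stepwords),
    preset = preset)
  if (!(p$s > 0 && p$s <= 1)) stop("s must be in (0, 1]")
  if (any(c(p$max_accepts, p$max_rejects, p$wordlength, p$stepwords) < 1)) {
    stop("max_accepts, max_rejects, wordlength and stepwords must be >= 1")
  }
  structure(p, class = "clustering_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise percent identity under semi-global alignment
#'
#' Aligns two sequences with free end gaps (overlap alignment; match +1,
#' mismatch 0, gap -1) and returns matches divided by alignment columns,
#' terminal gap columns excluded. `N` participates in the alignment but
#' never counts as a match.
#'
#' @param query,target Single sequences (plain strings or length-1 named
#'   vectors as returned by [read_fasta()]).
#' @param details If `TRUE`, also return the optimal score and the match and
#'   column counts.
#' @return Identity in `[0, 1]`, or a list when `details = TRUE`.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")
#' @export
pairwise_identity <- function(query, target, details = FALSE) {
  res <- cpp_pairwise_identity(as.character(query)[1], as.character(target)[1])
  if (details) res else res$identity
}

#' k-mer index over a set of target sequences
#'
#' @param targets Named character vector of target sequences.
#' @param wordlength k-mer size.
#' @return An object of class `kmer_index` holding the targets, word length
#'   and per-target unique-word counts.
#' @export
kmer_index <- function(targets, wordlength) {
  assert_seqs(targets, "targets")
  wordlength <- as.integer(wordlength)
  if (wordlength < 1) stop("wordlength must be >= 1")
  uw <- vapply(targets, function(s) {
    L <- nchar(s)
    if (L < wordlength) 0L
    else length(unique(substring(s, 1:(L - wordlength + 1), wordlength:L)))
  }, integer(1))
  structure(list(targets = targets, wordlength = wordlength, unique_words = uw),
            class = "kmer_index")
}

#' Rank candidate targets for a query by shared unique k-mers
#'
#' Candidates are sorted by the number of distinct words shared with the
#' query, descending, ties broken by target insertion order. Query word
#' scanning stops after `stepwords * wordlength` query positions. Queries
#' shorter than the word length yield no candidates.
#'
#' @param query A single sequence.
#' @param index A [kmer_index].
#' @param stepwords Scanning cap (see [clustering_params()]).
#' @return Character vector of candidate target ids, best first.
#' @export
rank_candidates <- function(query, index, stepwords) {
  stopifnot(inherits(index, "kmer_index"))
  ord <- cpp_rank_candidates(as.character(query)[1], unname(index$targets),
                             index$wordlength, as.integer(stepwords))
  names(index$targets)[ord]
}

#' Closed-reference assignment of reads to reference centroids
#'
#' Each read is assigned to the best accepted reference centroid at identity
#' `>= s` (ties broken by candidate rank); reads with no accepted centroid
#' are failures. Candidate evaluation stops after `max_accepts` accepts or
#' `max_rejects` rejects. The result is independent of how reads are
#' partitioned across workers, so the work may be split freely.
#'
#' @param reads,reference Named character vectors of sequences.
#' @param params A [clustering_params].
#' @param workers Number of chunks to split the reads into (results are
#'   merge-identical to the serial run).
#' @return List with `assignments` (data.frame: read_id, otu_id, identity)
#'   and `failures` (character vector of read ids, in input order).
#' @export
assign_closed_reference <- function(reads, reference, params = clustering_params(),
                                    workers = 1L) {
  assert_seqs(reads, "reads")
  assert_seqs(reference, "reference")
  if (length(reference) == 0) stop("reference must be non-empty")
  if (length(reads) == 0) {
    return(list(assignments = data.frame(read_id = character(), otu_id = character(),
                                         identity = numeric(), stringsAsFactors = FALSE),
                failures = character()))
  }
  workers <- max(1L, as.integer(workers))
  idx <- seq_along(reads)
  chunks <- split(idx, ceiling(idx / ceiling(length(idx) / workers)))
  hit <- integer(length(reads)); ident <- numeric(length(reads))
  for (ch in chunks) {
    res <- cpp_closed_ref(unname(reads[ch]), unname(reference), params$s,
                          params$max_accepts, params$max_rejects,
                          params$wordlength, params$stepwords)
    hit[ch] <- res$hit
    ident[ch] <- res$identity
  }
  ok <- !is.na(hit)
  list(
    assignments = data.frame(
      read_id = names(reads)[ok],
      otu_id = names(reference)[hit[ok]],
      identity = ident[ok],
      stringsAsFactors = FALSE),
    failures = names(reads)[!ok])
}

#' Greedy de novo clustering
#'
#' Reads are processed in input order. A read joins the best accepted
#' existing centroid at identity `>= s`, otherwise it founds a new OTU with
#' itself as centroid. OTU founding order equals first-member order.
#'
#' @inheritParams assign_closed_reference
#' @param otu_prefix Prefix for generated OTU ids; ids are
#'   `<prefix><i>` with `i` counting from `start_index` in founding order.
#' @param start_index First OTU index (default 0).
#' @param tier Provenance tier recorded for the resulting OTUs.
#' @param presort `"none"` (default: keep input order) or `"length"`
#'   (process longest reads first, stable within equal lengths), a
#'   uclust-style option for length-heterogeneous inputs.
#' @return An [otu_map] with centroids and tiers.
#' @export
cluster_de_novo <- function(reads, params = clustering_params(),
                            otu_prefix = "denovo", start_index = 0L,
                            tier = "new_reference",
                            presort = c("none", "length")) {
  presort <- match.arg(presort)
  assert_seqs(reads, "reads")
  if (length(reads) == 0) return(otu_map(stats::setNames(list(), character())))
  if (presort == "length") {
    reads <- reads[order(-nchar(reads))]   # order() is stable
  }
  res <- cpp_de_novo(unname(reads), params$s, params$max_accepts,
                     params$max_rejects, params$wordlength, params$stepwords)
  n_otu <- length(res$centroid_read)
  ids <- paste0(otu_prefix, seq.int(start_index, length.out = n_otu))
  otus <- split(names(reads), factor(res$cluster, levels = seq_len(n_otu)))
  names(otus) <- ids
  centroids <- stats::setNames(names(reads)[res$centroid_read], ids)
  otu_map(otus, centroids = centroids,
          tiers = stats::setNames(rep(tier, n_otu), ids))
}
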