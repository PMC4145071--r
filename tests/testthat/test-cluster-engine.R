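exhaustive <- clustering_params(preset = "exhaustive")

test_that("pairwise identity matches analytic values and the alignment oracle", {
  set.seed(21)
  a <- rand_dna(100)
  expect_equal(pairwise_identity(a, a), 1.0)
  expect_equal(pairwise_identity(a, mutate_dna(a, nsub = 1)), 0.99)
  expect_equal(pairwise_identity(a, mutate_dna(a, nsub = 5)), 0.95)

  # internal deletion: value must equal the full DP oracle's
  b <- mutate_dna(a, del_at = 40, del_len = 2)
  expect_equal(pairwise_identity(b, a), oracle_identity(b, a))

  # randomized agreement with the independent wavefront oracle, plus
  # score agreement with Biostrings overlap alignment (tie-free quantity)
  for (z in 1:15) {
    x <- rand_dna(80)
    y <- if (z %% 3 == 0) rand_dna(80) else
      mutate_dna(x, nsub = sample(0:10, 1),
                 del_at = if (z %% 2) 20 else NULL, del_len = sample(0:3, 1))
    eng <- pairwise_identity(x, y, details = TRUE)
    ora <- oracle_align(x, y)
    expect_equal(eng$identity, ora$identity)
    expect_identical(eng$score, ora$score)
    bs <- Biostrings::pairwiseAlignment(
      x, y, type = "overlap",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = 0, baseOnly = TRUE),
      gapOpening = 0, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(eng$score, bs)
    expect_equal(pairwise_identity(x, y), pairwise_identity(y, x))
  }
})

test_that("N bases align but never count as matches", {
  a <- "ACGTACGTAC"
  b <- sub("G", "N", a)
  expect_equal(pairwise_identity(a, b), 0.9)
})

test_that("candidate ranking follows shared-word counts with insertion-order ties", {
  set.seed(31)
  targets <- stats::setNames(replicate(5, rand_dna(60)), paste0("t", 1:5))
  idx <- kmer_index(targets, wordlength = 8)

  expect_identical(rank_candidates(targets[["t3"]], idx, stepwords = 100)[1], "t3")
  expect_length(rank_candidates(paste(rep("A", 60), collapse = ""), idx, 100), 0)
  expect_length(rank_candidates("ACG", idx, 100), 0)  # shorter than wordlength

  # randomized agreement with a brute-force set-intersection oracle
  for (z in 1:10) {
    q <- mutate_dna(targets[[sample(5, 1)]], nsub = sample(0:25, 1))
    got <- rank_candidates(q, idx, stepwords = 100)
    counts <- oracle_shared_words(q, targets, k = 8)
    want <- names(sort(-counts[counts > 0]))  # stable sort keeps t-order on ties
    expect_identical(got, want)
  }
})

test_that("planted shared-word counts order candidates correctly", {
  # three targets constructed to share 7, 3 and 5 distinct 8-mers with the query
  set.seed(41)
  q <- rand_dna(64)
  piece <- function(nshare) {
    # copy a prefix long enough to contain nshare+7 positions -> nshare 8-mers
    paste0(substr(q, 1, nshare + 7), rand_dna(40))
  }
  targets <- c(t1 = piece(7), t2 = piece(3), t3 = piece(5))
  counts <- oracle_shared_words(q, targets, k = 8)
  expect_identical(unname(counts), c(7L, 3L, 5L))
  got <- rank_candidates(q, kmer_index(targets, 8), stepwords = 100)
  expect_identical(got, c("t1", "t3", "t2"))
})

test_that("stepwords caps how much of the query is scanned for words", {
  set.seed(43)
  targets <- c(tail_only = paste0(rand_dna(60)))
  # query shares words with the target only beyond the capped region
  q <- paste0(rand_dna(40), targets[["tail_only"]])
  idx <- kmer_index(targets, wordlength = 8)
  expect_length(rank_candidates(q, idx, stepwords = 2), 0)   # cap = 16 positions
  expect_identical(rank_candidates(q, idx, stepwords = 100), "tail_only")
})

test_that("closed-reference assignment matches analytic cases", {
  set.seed(51)
  ref <- stats::setNames(replicate(3, rand_dna(100)), c("G1", "G2", "G3"))
  r_same <- stats::setNames(ref[["G1"]], "S1_1")
  res <- assign_closed_reference(r_same, ref, exhaustive)
  expect_identical(res$assignments$otu_id, "G1")
  expect_equal(res$assignments$identity, 1.0)

  r_far <- stats::setNames(mutate_dna(ref[["G2"]], nsub = 5), "S1_2")
  res2 <- assign_closed_reference(r_far, ref["G2"], exhaustive)
  expect_identical(res2$failures, "S1_2")
  expect_error(assign_closed_reference(r_same, ref[0]), "non-empty")
})

test_that("exhaustive closed-reference equals the all-pairs alignment oracle", {
  set.seed(61)
  refs <- stats::setNames(replicate(10, rand_dna(120)), paste0("G", 1:10))
  reads <- character(50)
  for (i in 1:50) {
    reads[i] <- if (i %% 5 == 0) rand_dna(120) else
      mutate_dna(refs[[sample(10, 1)]], nsub = sample(0:6, 1))
  }
  names(reads) <- paste0("S1_", 1:50)
  res <- assign_closed_reference(reads, refs, exhaustive)
  ora <- oracle_all_pairs(reads, refs, s = 0.97)

  expect_setequal(res$failures, names(reads)[is.na(ora[, "hit"])])
  for (k in seq_len(nrow(res$assignments))) {
    rid <- res$assignments$read_id[k]
    expect_equal(res$assignments$identity[k], unname(ora[rid, "best"]))
    # assigned centroid achieves the oracle's best identity
    expect_equal(
      oracle_identity(reads[[rid]], refs[[res$assignments$otu_id[k]]]),
      unname(ora[rid, "best"]))
  }
})

test_that("closed-reference assignments are identical across worker partitions", {
  set.seed(71)
  refs <- stats::setNames(replicate(8, rand_dna(100)), paste0("G", 1:8))
  reads <- stats::setNames(
    vapply(sample(8, 40, replace = TRUE),
           function(i) mutate_dna(refs[[i]], nsub = sample(0:4, 1)), character(1)),
    paste0("S1_", 1:40))
  base <- assign_closed_reference(reads, refs, clustering_params())
  for (w in c(2, 7)) {
    expect_identical(assign_closed_reference(reads, refs, clustering_params(),
                                             workers = w), base)
  }
})

test_that("de novo clustering recovers planted centers and matches the greedy oracle", {
  expect_length(cluster_de_novo(character(0))$otus, 0)

  reads3 <- stats::setNames(rep(rand_dna(80), 3), paste0("S1_", 1:3))
  m3 <- cluster_de_novo(reads3, exhaustive)
  expect_length(m3$otus, 1)
  expect_identical(unname(m3$centroids[1]), "S1_1")
  expect_identical(m3$otus[[1]], paste0("S1_", 1:3))

  set.seed(81)
  c1 <- rand_dna(150)
  c2 <- mutate_dna(c1, nsub = 30)    # 20% divergent centers
  truth <- sample(rep(1:2, each = 20))
  reads <- stats::setNames(
    vapply(truth, function(t) mutate_dna(if (t == 1) c1 else c2,
                                         nsub = sample(0:1, 1)), character(1)),
    paste0("S1_", 1:40))
  m <- cluster_de_novo(reads, exhaustive)
  expect_length(m$otus, 2)
  got <- canonical_partition(m)
  want <- lapply(split(names(reads), truth), sort)
  expect_setequal(got, unname(want))

  ora <- oracle_greedy_denovo(reads, s = 0.97)
  expect_identical(as.vector(table(ora$assign)),
                   unname(lengths(m$otus)))
})

test_that("every emitted assignment re-verifies at >= s under all presets", {
  set.seed(91)
  refs <- stats::setNames(replicate(6, rand_dna(120)), paste0("G", 1:6))
  reads <- stats::setNames(
    c(vapply(sample(6, 30, replace = TRUE),
             function(i) mutate_dna(refs[[i]], nsub = sample(0:8, 1)), character(1)),
      replicate(5, rand_dna(120))),
    paste0("S1_", 1:35))
  for (preset in c("slow", "fast", "exhaustive")) {
    p <- clustering_params(preset = preset)
    res <- assign_closed_reference(reads, refs, p)
    for (k in seq_len(nrow(res$assignments))) {
      id <- oracle_identity(reads[[res$assignments$read_id[k]]],
                            refs[[res$assignments$otu_id[k]]])
      expect_gte(id, 0.97)
      expect_equal(id, res$assignments$identity[k])
    }
    m <- cluster_de_novo(reads, p)
    for (oid in names(m$otus)) {
      for (rid in m$otus[[oid]]) {
        expect_gte(oracle_identity(reads[[rid]], reads[[m$centroids[[oid]]]]), 0.97)
      }
    }
  }
})

test_that("optional length presort reorders processing but stays sound", {
  set.seed(95)
  base <- rand_dna(120)
  reads <- stats::setNames(
    c(substr(base, 1, 80), base, mutate_dna(base, nsub = 1)),
    c("S1_1", "S1_2", "S1_3"))
  m <- cluster_de_novo(reads, clustering_params(preset = "exhaustive"),
                       presort = "length")
  # the longest read founds the first OTU even though it is second in input
  expect_identical(unname(m$centroids[1]), "S1_2")
  for (oid in names(m$otus)) {
    for (rid in m$otus[[oid]]) {
      expect_gte(oracle_identity(reads[[rid]], reads[[m$centroids[[oid]]]]), 0.97)
    }
  }
})
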