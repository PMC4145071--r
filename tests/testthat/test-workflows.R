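exhaustive_wp <- function(...) {
  workflow_params(clustering = clustering_params(preset = "exhaustive"), ...)
}

make_mixed_fixture <- function(seed = 101, n_ref = 6, reads_per_kind = 10) {
  set.seed(seed)
  refs <- stats::setNames(replicate(n_ref, rand_dna(120)), paste0("G", seq_len(n_ref)))
  novel <- mutate_dna(refs[[1]], nsub = 40)            # ~33% divergent lineage
  reads <- c(
    vapply(sample(n_ref, reads_per_kind, replace = TRUE),
           function(i) mutate_dna(refs[[i]], nsub = sample(0:2, 1)), character(1)),
    vapply(seq_len(reads_per_kind),
           function(i) mutate_dna(novel, nsub = sample(0:2, 1)), character(1)))
  samp <- sample(rep(c("SA", "SB"), length.out = length(reads)))
  names(reads) <- paste0(samp, "_", seq_along(reads))
  list(refs = refs, reads = reads)
}

test_that("prefilter keeps matching reads and discards verified contaminants", {
  set.seed(111)
  refs <- stats::setNames(replicate(4, rand_dna(120)), paste0("G", 1:4))
  good <- stats::setNames(refs[[2]], "SA_1")
  # construct a contaminant verified < 0.60 to every reference by the oracle
  repeat {
    cont <- rand_dna(120)
    if (max(vapply(refs, function(r) oracle_identity(cont, r), numeric(1))) < 0.60) break
  }
  reads <- c(good, stats::setNames(cont, "SA_2"))
  pf <- prefilter_reads(reads, refs, identity = 0.60,
                        clustering_params(preset = "exhaustive"))
  expect_identical(names(pf$kept), "SA_1")
  expect_identical(names(pf$discarded), "SA_2")

  pf0 <- prefilter_reads(reads, refs, identity = 0)
  expect_identical(pf0$kept, reads)
  expect_length(pf0$discarded, 0)
})

test_that("failure subsampling is exact, seeded and order-preserving", {
  ids <- paste0("r", 1:10)
  full <- subsample_failures(ids, 1.0, seed = 5)
  expect_identical(full$subsample, ids)      # original order kept
  expect_length(full$remainder, 0)

  half <- subsample_failures(ids, 0.5, seed = 5)
  expect_length(half$subsample, 5)
  expect_length(intersect(half$subsample, half$remainder), 0)
  expect_setequal(c(half$subsample, half$remainder), ids)
  expect_identical(subsample_failures(ids, 0.5, seed = 5), half)

  # floor of one whenever failures exist and fraction > 0
  expect_length(subsample_failures(ids[1:3], 0.01, seed = 1)$subsample, 1)
  expect_length(subsample_failures(character(0), 0.5, seed = 1)$subsample, 0)
})

test_that("subsample inclusion frequencies match the binomial oracle", {
  items <- paste0("x", 1:4)
  n_trials <- 10000
  hits <- numeric(4)
  for (t in seq_len(n_trials)) {
    s <- subsample_failures(items, 0.5, seed = t)$subsample
    hits <- hits + items %in% s
  }
  p_hat <- hits / n_trials
  sigma <- sqrt(0.5 * 0.5 / n_trials)
  expect_true(all(abs(p_hat - 0.5) <= 3 * sigma))
})

test_that("closed-reference workflow conserves reads and uses reference ids only", {
  fx <- make_mixed_fixture()
  wp <- exhaustive_wp()

  all_hit <- fx$reads[1:10]
  res <- pick_closed_reference(all_hit, fx$refs, wp)
  expect_equal(sum(res$table_full), length(all_hit))
  expect_true(all(rownames(res$table_full) %in% names(fx$refs)))

  none <- stats::setNames(replicate(5, rand_dna(120)), paste0("SA_", 1:5))
  res0 <- pick_closed_reference(none, fx$refs, wp)
  expect_identical(nrow(res0$table_full), 0L)
  expect_setequal(res0$unmatched, names(none))

  mixed <- pick_closed_reference(fx$reads, fx$refs, wp)
  expect_equal(sum(mixed$table_full) + length(mixed$unmatched) +
                 length(mixed$prefilter_discards), length(fx$reads))
})

test_that("de novo workflow mirrors the clustering engine", {
  fx <- make_mixed_fixture()
  wp <- exhaustive_wp()
  res <- pick_de_novo(fx$reads, wp)
  eng <- cluster_de_novo(fx$reads, wp$clustering)
  expect_identical(unname(lapply(res$otu_map$otus, identity)),
                   unname(lapply(eng$otus, identity)))
  expect_true(all(res$otu_map$tiers == "new_reference"))
  expect_equal(sum(res$table_full), length(fx$reads))
})

test_that("classic open-reference degenerates to closed and de novo at the limits", {
  fx <- make_mixed_fixture()
  wp <- exhaustive_wp()

  all_hit <- fx$reads[1:10]
  cl <- pick_classic_open_reference(all_hit, fx$refs, wp)
  cr <- pick_closed_reference(all_hit, fx$refs, wp)
  expect_identical(cl$otu_map$otus, cr$otu_map$otus)

  none <- stats::setNames(replicate(6, rand_dna(120)), paste0("SA_", 1:6))
  cl0 <- pick_classic_open_reference(none, fx$refs, wp)
  dn0 <- pick_de_novo(none, wp)
  expect_identical(canonical_partition(cl0$otu_map), canonical_partition(dn0$otu_map))

  mixed <- pick_classic_open_reference(fx$reads, fx$refs, wp)
  expect_equal(sum(mixed$table_full), length(fx$reads))
})

test_that("subsampled open-reference: tiers, naming, determinism, conservation", {
  fx <- make_mixed_fixture(seed = 131)
  wp <- exhaustive_wp(subsample_fraction = 0.5, seed = 9)
  res <- pick_subsampled_open_reference(fx$reads, fx$refs, wp)

  expect_equal(sum(res$table_full), length(fx$reads))
  tiers <- res$otu_map$tiers
  expect_length(intersect(names(tiers)[tiers == "reference"],
                          names(tiers)[tiers != "reference"]), 0)
  new_ids <- names(tiers)[tiers == "new_reference"]
  expect_true(all(grepl("^New\\.ReferenceOTU[0-9]+$", new_ids)))
  expect_true(all(grepl("^New\\.CleanUpReferenceOTU[0-9]+$",
                        names(tiers)[tiers == "cleanup"])))
  if (length(new_ids) > 0) expect_identical(new_ids[1], "New.ReferenceOTU0")

  # every member re-verifies at >= s against its centroid
  for (oid in names(tiers)[tiers != "reference"]) {
    cent <- fx$reads[[res$otu_map$centroids[[oid]]]]
    for (rid in res$otu_map$otus[[oid]]) {
      expect_gte(oracle_identity(fx$reads[[rid]], cent), 0.97)
    }
  }

  # fixed seed => identical result object
  expect_identical(pick_subsampled_open_reference(fx$reads, fx$refs, wp), res)
  # worker count must not change the outcome
  wp2 <- wp; wp2$workers <- 3L
  res2 <- pick_subsampled_open_reference(fx$reads, fx$refs, wp2)
  res2$params <- res$params
  expect_identical(res2, res)

  expect_error(pick_subsampled_open_reference(fx$reads, fx$refs[0], wp), "non-empty")
})

test_that("all reads matching the reference yields a pure closed-reference result", {
  fx <- make_mixed_fixture()
  wp <- exhaustive_wp()
  all_hit <- fx$reads[1:10]
  ss <- pick_subsampled_open_reference(all_hit, fx$refs, wp)
  cr <- pick_closed_reference(all_hit, fx$refs, wp)
  expect_identical(ss$otu_map$otus, cr$otu_map$otus)
  expect_length(ss$new_centroids, 0)
  expect_true(all(ss$otu_map$tiers == "reference"))
})

test_that("full subsampling reproduces the classic open-reference partition", {
  fx <- make_mixed_fixture(seed = 141, n_ref = 5, reads_per_kind = 15)
  wp <- exhaustive_wp(subsample_fraction = 1.0, seed = 3)
  ss <- pick_subsampled_open_reference(fx$reads, fx$refs, wp)
  cl <- pick_classic_open_reference(fx$reads, fx$refs, wp)
  expect_identical(canonical_partition(ss$otu_map), canonical_partition(cl$otu_map))
})

test_that("zero subsampling also degenerates to the classic partition", {
  fx <- make_mixed_fixture(seed = 151)
  wp <- exhaustive_wp(subsample_fraction = 0, seed = 3)
  ss <- pick_subsampled_open_reference(fx$reads, fx$refs, wp)
  cl <- pick_classic_open_reference(fx$reads, fx$refs, wp)
  expect_identical(canonical_partition(ss$otu_map), canonical_partition(cl$otu_map))
  expect_true(all(ss$otu_map$tiers %in% c("reference", "cleanup")))
})

test_that("minimum-count filter keeps row sums >= c and matches a row-sum oracle", {
  counts <- matrix(c(1L, 1L, 0L, 0L, 1L, 0L), 3, 2,
                   dimnames = list(c("O1", "O2", "O3"), c("SA", "SB")))
  tab <- otu_table(counts)
  expect_identical(filter_min_count(tab, 0), tab)
  expect_identical(rownames(filter_min_count(tab, 2)), "O2")

  set.seed(161)
  big <- otu_table(matrix(rpois(60, 1), 12, 5,
                          dimnames = list(paste0("O", 1:12), paste0("S", 1:5))))
  for (k in 0:4) {
    expect_identical(rownames(filter_min_count(big, k)),
                     rownames(big)[rowSums(big) >= k])
  }
})

test_that("iterative reference expansion keeps OTU definitions stable", {
  fx <- make_mixed_fixture(seed = 171)
  wp <- exhaustive_wp(subsample_fraction = 1.0, seed = 2)
  run1 <- pick_subsampled_open_reference(fx$reads, fx$refs, wp)
  expect_identical(iterative_update_reference(fx$refs,
                     pick_closed_reference(fx$reads[1:10], fx$refs, wp)), fx$refs)

  ref2 <- iterative_update_reference(fx$refs, run1)
  new_ids <- grep("^New\\.", names(ref2), value = TRUE)
  expect_gt(length(new_ids), 0)

  # copies of a run-1 novel centroid land in the same OTU id, reference tier
  target <- new_ids[1]
  copies <- stats::setNames(rep(ref2[[target]], 3), paste0("SB_", 101:103))
  run2 <- pick_subsampled_open_reference(copies, ref2, wp)
  expect_identical(rownames(run2$table_full), target)
  expect_identical(unname(run2$otu_map$tiers[target]), "reference")

  # run-2 new OTUs never reuse run-1 ids
  other <- stats::setNames(replicate(4, rand_dna(120)), paste0("SB_", 201:204))
  run2b <- pick_subsampled_open_reference(other, ref2, wp)
  new2 <- names(run2b$otu_map$tiers)[run2b$otu_map$tiers != "reference"]
  expect_length(intersect(new2, names(ref2)), 0)
})

test_that("two iterative runs agree with one pooled run on run-1 assignments", {
  fx <- make_mixed_fixture(seed = 181, n_ref = 4, reads_per_kind = 8)
  wp <- exhaustive_wp(subsample_fraction = 1.0, seed = 6)
  half <- length(fx$reads) %/% 2
  r1 <- fx$reads[1:half]; r2 <- fx$reads[(half + 1):length(fx$reads)]

  run1 <- pick_subsampled_open_reference(r1, fx$refs, wp)
  ref2 <- iterative_update_reference(fx$refs, run1)
  run2 <- pick_subsampled_open_reference(r2, ref2, wp)
  pooled <- pick_subsampled_open_reference(c(r1, r2), fx$refs, wp)

  otu_of <- function(res) {
    out <- rep(NA_character_, 0)
    for (oid in names(res$otu_map$otus)) {
      out[res$otu_map$otus[[oid]]] <- oid
    }
    out
  }
  o1 <- otu_of(run1); op <- otu_of(pooled)
  expect_identical(o1[names(r1)], op[names(r1)])
})
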