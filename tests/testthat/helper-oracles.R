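# Independent oracles used across the suite. These re-implement the declared
# alignment/identity definition (semi-global, free end gaps, match +1,
# mismatch 0, gap -1; identity = matches / columns excluding terminal gaps;
# endpoint = first maximum over bottom row then right column, strict
# improvement; traceback prefers diagonal, then up, then left) with a
# different algorithm (anti-diagonal wavefront over an R matrix) so that
# engine and oracle share only the definition, not the code.

oracle_align <- function(a, b) {
  if (b < a) { tmp <- a; a <- b; b <- tmp }  # canonical order, as declared
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(av); n <- length(bv)
  H <- matrix(0L, m + 1, n + 1)
  for (d in 2:(m + n)) {
    i <- max(1, d - n):min(m, d - 1)
    j <- d - i
    sub <- as.integer(av[i] == bv[j] & av[i] != "N")
    H[cbind(i + 1, j + 1)] <- pmax(H[cbind(i, j)] + sub,
                                   H[cbind(i, j + 1)] - 1L,
                                   H[cbind(i + 1, j)] - 1L)
  }
  bi <- m; bj <- 0; bs <- H[m + 1, 1]
  for (j in 0:n) if (H[m + 1, j + 1] > bs) { bs <- H[m + 1, j + 1]; bi <- m; bj <- j }
  for (i in 0:(m - 1)) if (H[i + 1, n + 1] > bs) { bs <- H[i + 1, n + 1]; bi <- i; bj <- n }
  i <- bi; j <- bj; matches <- 0L; cols <- 0L
  while (i > 0 && j > 0) {
    sub <- as.integer(av[i] == bv[j] & av[i] != "N")
    if (H[i + 1, j + 1] == H[i, j] + sub) {
      matches <- matches + sub; cols <- cols + 1L; i <- i - 1; j <- j - 1
    } else if (H[i + 1, j + 1] == H[i, j + 1] - 1L) {
      cols <- cols + 1L; i <- i - 1
    } else {
      cols <- cols + 1L; j <- j - 1
    }
  }
  list(identity = if (cols > 0) matches / cols else 0,
       score = bs, matches = matches, columns = cols)
}

oracle_identity <- function(a, b) oracle_align(a, b)$identity

# All-pairs closed-reference oracle: align every read to every reference,
# take the best hit >= s (NA if none). Returns best identity and whether any
# reference achieves it.
oracle_all_pairs <- function(reads, refs, s) {
  t(vapply(reads, function(q) {
    ids <- vapply(refs, function(r) oracle_identity(q, r), numeric(1))
    best <- max(ids)
    c(best = best, hit = if (best >= s) which.max(ids) else NA_real_)
  }, c(best = 0, hit = 0)))
}

# Order-respecting greedy de novo oracle built on all-pairs alignment.
oracle_greedy_denovo <- function(reads, s) {
  centroids <- integer(0)
  assign <- integer(length(reads))
  for (i in seq_along(reads)) {
    best <- -1; best_c <- NA_integer_
    for (ci in seq_along(centroids)) {
      id <- oracle_identity(reads[[i]], reads[[centroids[ci]]])
      if (id >= s && id > best) { best <- id; best_c <- ci }
    }
    if (is.na(best_c)) {
      centroids <- c(centroids, i)
      assign[i] <- length(centroids)
    } else {
      assign[i] <- best_c
    }
  }
  list(assign = assign, centroids = centroids)
}

# brute-force shared-unique-kmer counts (candidate-ranking oracle)
oracle_shared_words <- function(query, targets, k, stepwords = NULL) {
  kmers <- function(s, cap = NULL) {
    L <- nchar(s)
    if (L < k) return(character(0))
    starts <- 1:(L - k + 1)
    if (!is.null(cap)) starts <- starts[starts <= cap]
    unique(substring(s, starts, starts + k - 1))
  }
  qk <- kmers(query, cap = if (is.null(stepwords)) NULL else stepwords * k)
  vapply(targets, function(t) length(intersect(qk, kmers(t))), integer(1))
}

# local sequence helpers, independent of the package's generator
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

mutate_dna <- function(seq, nsub = 0, del_at = NULL, del_len = 0) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (nsub > 0) {
    pos <- sample(length(v), nsub)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  if (!is.null(del_at) && del_len > 0) v <- v[-(del_at:(del_at + del_len - 1))]
  paste(v, collapse = "")
}

canonical_partition <- function(map) {
  parts <- lapply(unname(map$otus), function(x) sort(x))
  parts <- parts[order(vapply(parts, `[`, character(1), 1))]
  parts
}
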