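#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercase-normalized and restricted to the alphabet
#' `{A,C,G,T,N}`. Record order follows file order exactly; order matters
#' downstream because greedy clustering is order-dependent.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences; names are the record ids
#'   (first whitespace-delimited token of each header).
#' @examples
#' f <- tempfile(fileext = ".fna")
#' writeLines(c(">r1", "acgt", ">r2", "GGCC"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for id: ", ids[which(nchar(seqs) == 0)[1]])
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}: ", ids[which(bad)[1]])
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  assert_seqs(seqs)
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Infer sample ids from read ids
#'
#' Read ids are assumed to follow the QIIME demultiplexing convention
#' `sampleid_serial`; the sample id is everything before the *last*
#' underscore. An explicit mapping overrides inference.
#'
#' @param read_ids Character vector of read ids.
#' @param map Optional named character vector `read_id -> sample_id`; must
#'   cover every read id.
#' @return Named character vector `read_id -> sample_id`.
#' @export
sample_assignment <- function(read_ids, map = NULL) {
  if (!is.null(map)) {
    missing <- setdiff(read_ids, names(map))
    if (length(missing) > 0) {
      stop("no sample assignment for read: ", missing[1])
    }
    out <- map[read_ids]
    names(out) <- read_ids
    return(out)
  }
  has_us <- grepl("_", read_ids)
  if (!all(has_us)) {
    stop("cannot infer sample id (no underscore) for read: ",
         read_ids[which(!has_us)[1]])
  }
  out <- sub("_[^_]*$", "", read_ids)
  names(out) <- read_ids
  out
}

#' Write an OTU map (one OTU per line: otu id, then member read ids, tab-separated)
#'
#' @param map An [otu_map] object (or bare named list of read-id vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_map <- function(map, path) {
  otus <- if (inherits(map, "otu_map")) map$otus else map
  lines <- vapply(seq_along(otus), function(i) {
    paste(c(names(otus)[i], otus[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an OTU map written by [write_otu_map()]
#'
#' Centroid and tier provenance are not part of the on-disk format; the
#' returned object carries membership only.
#'
#' @param path Path to an OTU map file.
#' @return An [otu_map] object.
#' @export
read_otu_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  otus <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) {
      stop("malformed OTU map line ", i, ": fewer than 2 fields")
    }
    ids[i] <- fields[1]
    otus[[i]] <- fields[-1]
  }
  names(otus) <- ids
  otu_map(otus)
}

#' OTU membership map with provenance
#'
#' A partition of read ids into named OTUs, optionally carrying the centroid
#' sequence id and provenance tier (`reference`, `new_reference`, `cleanup`)
#' of each OTU.
#'
#' @param otus Named list; each element is a character vector of member read ids.
#' @param centroids Optional named character vector `otu_id -> centroid id`.
#' @param tiers Optional named character vector `otu_id -> tier`.
#' @return An object of class `otu_map`.
#' @export
otu_map <- function(otus, centroids = NULL, tiers = NULL) {
  stopifnot(is.list(otus))
  if (length(otus) > 0 && (is.null(names(otus)) || anyDuplicated(names(otus)))) {
    stop("OTU ids must be unique and non-empty")
  }
  members <- unlist(otus, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("read assigned to more than one OTU: ",
         members[duplicated(members)][1])
  }
  if (!is.null(tiers)) {
    bad <- setdiff(unique(tiers), c("reference", "new_reference", "cleanup"))
    if (length(bad) > 0) stop("unknown tier: ", bad[1])
  }
  structure(list(otus = otus, centroids = centroids, tiers = tiers),
            class = "otu_map")
}

#' @export
print.otu_map <- function(x, ...) {
  cat("otu_map:", length(x$otus), "OTUs,",
      length(unlist(x$otus, use.names = FALSE)), "reads\n")
  if (!is.null(x$tiers)) print(table(x$tiers))
  invisible(x)
}

#' OTU-by-sample count table
#'
#' A non-negative integer matrix with OTU ids as rownames and sample ids as
#' colnames, optionally carrying a taxonomy map
#' (`otu_id -> semicolon-delimited lineage`) as an attribute.
#'
#' @param counts Integer matrix (OTU x sample) with dimnames.
#' @param taxonomy Optional named character vector of lineages.
#' @return An object of class `otu_table` (a matrix).
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts))) stop("counts needs rownames (OTU ids)")
  if (ncol(counts) > 0 && is.null(colnames(counts))) stop("counts needs colnames (sample ids)")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("OTU and sample ids must be unique")
  }
  if (length(counts) > 0) {
    if (any(counts < 0) || any(counts != round(counts))) {
      stop("counts must be non-negative integers")
    }
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) attr(counts, "taxonomy") <- taxonomy
  class(counts) <- c("otu_table", class(counts))
  counts
}

#' Write an OTU table
#'
#' The `classic_tsv` dialect starts with a `#OTU ID` header line and holds
#' one row per OTU with integer counts, plus an optional trailing `taxonomy`
#' column. The `json` dialect is a minimal sparse row/col/value layout.
#'
#' @param table An [otu_table].
#' @param path Output path.
#' @param dialect `"classic_tsv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, dialect = c("classic_tsv", "json")) {
  dialect <- match.arg(dialect)
  tax <- attr(table, "taxonomy")
  if (dialect == "classic_tsv") {
    header <- paste(c("#OTU ID", colnames(table),
                      if (!is.null(tax)) "taxonomy"), collapse = "\t")
    body <- vapply(seq_len(nrow(table)), function(i) {
      oid <- rownames(table)[i]
      paste(c(oid, as.integer(table[i, ]),
              if (!is.null(tax)) unname(tax[oid])), collapse = "\t")
    }, character(1))
    writeLines(c(header, body), path)
  } else {
    nz <- which(unclass(table) != 0, arr.ind = TRUE)
    obj <- list(otu_ids = rownames(table), sample_ids = colnames(table),
                rows = as.integer(nz[, 1]), cols = as.integer(nz[, 2]),
                values = as.integer(table[nz]))
    if (!is.null(tax)) obj$taxonomy <- as.list(tax)
    jsonlite::write_json(obj, path, auto_unbox = FALSE)
  }
  invisible(path)
}

#' Read an OTU table written by [write_otu_table()]
#'
#' The dialect is auto-detected (`#OTU ID` header vs JSON).
#'
#' @param path Path to an OTU table file.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 1 && startsWith(first, "{")) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    counts <- matrix(0L, nrow = length(obj$otu_ids), ncol = length(obj$sample_ids),
                     dimnames = list(obj$otu_ids, obj$sample_ids))
    if (length(obj$rows) > 0) {
      counts[cbind(obj$rows, obj$cols)] <- as.integer(obj$values)
    }
    tax <- if (!is.null(obj$taxonomy)) unlist(obj$taxonomy) else NULL
    return(otu_table(counts, taxonomy = tax))
  }
  lines <- readLines(path)
  hdr_i <- which(startsWith(lines, "#OTU ID"))
  if (length(hdr_i) == 0) stop("not a classic OTU table: missing '#OTU ID' header")
  hdr <- strsplit(lines[hdr_i[1]], "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(hdr_i[1])]
  body <- body[nzchar(body)]
  has_tax <- length(hdr) > 1 && tolower(hdr[length(hdr)]) == "taxonomy"
  sample_ids <- hdr[-1]
  if (has_tax) sample_ids <- sample_ids[-length(sample_ids)]
  n <- length(body)
  counts <- matrix(0L, nrow = n, ncol = length(sample_ids),
                   dimnames = list(rep("", n), sample_ids))
  tax <- if (has_tax) character(n) else NULL
  for (i in seq_len(n)) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    want <- 1 + length(sample_ids) + as.integer(has_tax)
    if (length(fields) != want) stop("malformed OTU table line ", i + hdr_i[1])
    rownames(counts)[i] <- fields[1]
    vals <- suppressWarnings(as.numeric(fields[2:(1 + length(sample_ids))]))
    if (anyNA(vals) || any(vals < 0) || any(vals != round(vals))) {
      stop("negative or non-integer count at line ", i + hdr_i[1])
    }
    counts[i, ] <- as.integer(vals)
    if (has_tax) tax[i] <- fields[length(fields)]
  }
  if (has_tax) names(tax) <- rownames(counts)
  otu_table(counts, taxonomy = tax)
}

#' Read a rooted newick tree
#'
#' Missing branch lengths are set to 0. Tip labels must be unique.
#'
#' @param path Path to a newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop("newick parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error in ", path)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label: ", tree$tip.label[duplicated(tree$tip.label)][1])
  }
  tree
}

#' Read/write a taxonomy map (otu id, tab, semicolon-delimited lineage)
#'
#' @param path Path to a two-column TSV.
#' @return Named character vector `otu_id -> lineage`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("taxonomy file needs two tab-separated columns")
  out <- df[[2]]
  names(out) <- df[[1]]
  out
}

#' @rdname read_taxonomy
#' @param taxonomy Named character vector of lineages.
#' @export
write_taxonomy <- function(taxonomy, path) {
  writeLines(paste(names(taxonomy), taxonomy, sep = "\t"), path)
  invisible(path)
}

#' Write/read a sample distance matrix as TSV with id header row and column
#'
#' @param dm Symmetric numeric matrix with matching dimnames.
#' @param path File path.
#' @return `write_distance_matrix` returns `path` invisibly;
#'   `read_distance_matrix` returns the matrix.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(id = rownames(dm), dm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
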