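# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# round-half-up for non-negative x
round_half_up <- function(x) floor(x + 0.5)

assert_seqs <- function(x, what = "sequences") {
  if (!is.character(x)) stop(what, " must be a named character vector")
  if (length(x) > 0) {
    if (is.null(names(x)) || any(names(x) == "") || anyNA(names(x))) {
      stop(what, " must have non-empty ids as names")
    }
    if (anyDuplicated(names(x))) {
      stop("duplicate ids in ", what, ": ",
           paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
    }
    if (any(nchar(x) == 0)) {
      stop("empty sequence for id: ", names(x)[which(nchar(x) == 0)[1]])
    }
  }
  invisible(x)
}
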