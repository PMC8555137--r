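# internal helpers shared across modules

#' @importFrom stats runif setNames predict sd
#' @importFrom utils head read.table write.table
NULL

# Run code with a private RNG stream, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# content hash for job plans (stable across sessions): md5 of the
# field string, via a scratch file (tools::md5sum only hashes files)
content_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(x, collapse = "\x1f"), tf)
  unname(tools::md5sum(tf))
}

# canonical unordered pair: lexicographically smaller id first
canonical_pairs <- function(u, v) {
  swap <- u > v
  tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  list(u = u, v = v)
}

edge_key <- function(u, v) {
  p <- canonical_pairs(u, v)
  paste(p$u, p$v, sep = "\t")
}

#' Edge length from interaction confidence
#'
#' Converts a confidence in (0, 1] to a non-negative length
#' `-log(confidence)`, the standard transform under which path length equals
#' the negative log reliability of the path (assuming independent edges).
#' Confidence 1 gives length 0.
#'
#' @param confidence numeric vector in (0, 1].
#' @return numeric vector of non-negative lengths.
#' @export
edge_length <- function(confidence) {
  stopifnot(all(confidence > 0 & confidence <= 1))
  -log(confidence)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# population standard deviation (divide by n, not n - 1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
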