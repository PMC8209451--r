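# Shared internal helpers.

#' @importFrom data.table data.table .N :=
NULL

.datatable.aware <- TRUE

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded package
#' operations never perturb the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
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
  expr
}

# Derive a stage seed (< 2^31) from a base seed and a small offset.
derive_seed <- function(seed, k) {
  (as.numeric(seed) %% 1000000000 + 1000003 * k) %% 2147483647
}

#' Count mismatching characters between equal-width string vectors
#'
#' Both vectors must contain strings of one common width. Vectorised via a
#' single raw-byte comparison, so it stays fast for hundreds of thousands of
#' reads.
#' @noRd
mismatch_count <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n == 0L) return(integer(0))
  w <- nchar(x[1L])
  if (w == 0L) return(integer(n))
  xr <- charToRaw(paste(x, collapse = ""))
  yr <- charToRaw(paste(y, collapse = ""))
  stopifnot(length(xr) == n * w, length(yr) == n * w)
  as.integer(colSums(matrix(xr != yr, nrow = w)))
}

# Decode a vector of Phred+33 quality strings into a list of integer vectors.
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

# Encode integer Phred scores as a Phred+33 string.
int_to_phred <- function(q) {
  intToUtf8(pmax(0L, as.integer(q)) + 33L)
}

# First TRUE column index per row of a logical matrix (NA if none).
row_first_true <- function(m) {
  idx <- col(m)
  idx[!m] <- NA_integer_
  out <- rep(NA_integer_, nrow(m))
  for (j in seq_len(ncol(m))) {
    hit <- is.na(out) & !is.na(idx[, j])
    out[hit] <- idx[hit, j]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
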