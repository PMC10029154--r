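#' @keywords internal
"_PACKAGE"

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG stream afterwards. All randomised entry points go through this
# so that a seed argument fully determines the output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Row-wise softmax with max-subtraction for numerical stability.
softmax_rows <- function(scores) {
  scores <- as.matrix(scores)
  m <- apply(scores, 1L, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

# Sort key for chromosome labels: numeric labels in numeric order, then
# non-numeric labels (X, Y, MT, ...) alphabetically after them.
chrom_sort_key <- function(chrom) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.numeric(chrom))
  key <- num
  nonnum <- is.na(num)
  if (any(nonnum)) {
    lab <- sort(unique(chrom[nonnum]))
    key[nonnum] <- max(c(0, num), na.rm = TRUE) + match(chrom[nonnum], lab)
  }
  key
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_breedid <- function(...) stop(..., call. = FALSE)
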