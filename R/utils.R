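# internal helpers shared across modules

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded operations do not disturb the
#' caller's RNG stream. A `NULL` seed evaluates the code as-is.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse complement of a DNA string (character scalar)
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Number of insertions / summed reads per closed interval
#'
#' `positions` must be sorted ascending; `reads` aligned with `positions`.
#' Returns a list with per-interval insertion and read totals. O(F + n).
#' @noRd
count_in_ranges <- function(positions, reads, starts, ends) {
  if (length(positions) == 0L) {
    z <- numeric(length(starts))
    return(list(n = z, reads = z))
  }
  lo <- findInterval(starts - 1L, positions)
  hi <- findInterval(ends, positions)
  creads <- c(0, cumsum(as.numeric(reads)))
  list(n = hi - lo, reads = creads[hi + 1L] - creads[lo + 1L])
}

#' Flagged-base count per closed interval from a logical mask
#' @noRd
masked_in_ranges <- function(mask, starts, ends) {
  cm <- c(0L, cumsum(as.integer(mask)))
  cm[ends + 1L] - cm[starts]
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}
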