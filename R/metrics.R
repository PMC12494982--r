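#' Per-feature linear density and read totals
#'
#' Linear density (LD) is the number of distinct inserted positions in a
#' genomic region divided by its length in bp. With `exclude_repeats = TRUE`
#' (the default used for per-feature metrics) repeated bases are removed
#' from both numerator and denominator, since mapping ambiguity prevents
#' placing insertions there; the genome-wide coverage figure is conventionally
#' reported without repeat exclusion (`exclude_repeats = FALSE`).
#'
#' A feature whose effective length is zero gets `ld = NA` (an undefined-LD
#' sentinel, never a silent 0).
#'
#' @param x A `tn_sample` or `tn_merged`.
#' @param features A `tn_features` table (or any data.frame with `id`,
#'   `start`, `end`).
#' @param mask Optional `tn_repeat_mask`.
#' @param exclude_repeats Drop repeat-flagged positions and bases.
#' @return A data.frame: `feature_id`, `length`, `effective_length`,
#'   `n_insertions`, `total_reads`, `ld`.
#' @export
linear_density <- function(x, features, mask = NULL, exclude_repeats = TRUE) {
  stopifnot(!is.null(x$positions))
  pos <- x$positions
  reads <- x$reads
  starts <- as.integer(features$start)
  ends <- as.integer(features$end)
  len <- ends - starts + 1L
  if (exclude_repeats && !is.null(mask)) {
    flags <- if (inherits(mask, "tn_repeat_mask")) mask$flags else mask
    keep <- !flags[pos]
    pos <- pos[keep]; reads <- reads[keep]
    eff <- len - masked_in_ranges(flags, starts, ends)
  } else {
    eff <- len
  }
  cnt <- count_in_ranges(pos, reads, starts, ends)
  ld <- ifelse(eff > 0L, cnt$n / eff, NA_real_)
  data.frame(feature_id = features$id, length = len, effective_length = eff,
             n_insertions = as.integer(cnt$n),
             total_reads = as.numeric(cnt$reads), ld = ld,
             stringsAsFactors = FALSE)
}

#' Reads per kilobase per million library reads
#'
#' RPKM of a region: reads mapping to insertions in the region, scaled by
#' region length in kb and library size in millions of reads.
#'
#' @param x A `tn_sample` or `tn_merged`.
#' @param features Feature table (`id`, `start`, `end`).
#' @param library_total_reads Library size; defaults to the sample total.
#' @return Numeric vector aligned with `features` rows.
#' @export
rpkm <- function(x, features, library_total_reads = sum(as.numeric(x$reads))) {
  if (library_total_reads <= 0) stop("library_total_reads must be > 0")
  starts <- as.integer(features$start); ends <- as.integer(features$end)
  len <- ends - starts + 1L
  if (any(len <= 0L)) stop("zero-length feature")
  cnt <- count_in_ranges(x$positions, x$reads, starts, ends)
  cnt$reads / ((len / 1000) * (library_total_reads / 1e6))
}

#' Normalize per-feature values by the gold non-essential mean
#'
#' Divides each feature's value by the mean value of a curated gold set of
#' known non-essential (NE) genes measured in the same sample, removing
#' sample-level differences in insertion coverage. Normalized values are
#' >= 0 and may exceed 1 when a feature is denser in insertions than NE
#' territory.
#'
#' @param values Named numeric vector (names are feature ids).
#' @param gold Character ids or logical vector marking the gold NE set.
#' @return The normalized named vector.
#' @export
ne_normalize <- function(values, gold) {
  if (is.character(gold)) {
    if (is.null(names(values))) stop("values must be named to use id-based gold")
    gold <- names(values) %in% gold
  }
  if (!any(gold)) stop("gold NE set is empty")
  m <- mean(values[gold], na.rm = TRUE)
  if (!is.finite(m) || m == 0) stop("gold NE mean is zero or undefined")
  values / m
}

#' Write a per-sample metrics table as TSV
#' @param metrics Data.frame from [linear_density()] (optionally with an
#'   `rpkm` column).
#' @param path Output path.
#' @export
write_metrics_table <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
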