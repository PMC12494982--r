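#' Genome container
#'
#' A minimal in-memory genome: an identifier, an upper-case DNA sequence
#' restricted to the alphabet ACGTN, and its length in bp. All coordinates in
#' the package are 1-based closed intervals, following GFF3 convention.
#'
#' @param sequence Character scalar, the genome sequence (ACGTN).
#' @param id Genome identifier.
#' @return An object of class `tn_genome` with fields `id`, `sequence`,
#'   `length`.
#' @export
tn_genome <- function(sequence, id = "genome") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("genome sequence contains characters outside ACGTN")
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "tn_genome")
}

#' @export
print.tn_genome <- function(x, ...) {
  cat(sprintf("<tn_genome> %s: %s bp\n", x$id, format(x$length, big.mark = ",")))
  invisible(x)
}

#' Read / write a genome as FASTA
#'
#' Thin wrappers over Biostrings. Only the first record of a multi-FASTA is
#' used for `read_genome_fasta()`.
#'
#' @param path File path.
#' @param genome A `tn_genome`.
#' @return `read_genome_fasta()` returns a `tn_genome`.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in FASTA: ", path)
  tn_genome(as.character(ss[[1L]]), id = sub("\\s.*$", "", names(ss)[1L]))
}

#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Label repeated genome positions with a k-mer sliding window
#'
#' Slides a window of `k` bp (default 21) over the genome, extracts each
#' window sequence, and looks for perfect matches of that sequence in the
#' genome and in its reverse complement. A window whose sequence occurs at
#' least twice across the two strands is "repeated": insertions there cannot
#' be mapped unambiguously, so downstream density denominators exclude these
#' bases.
#'
#' Two marking policies are supported. `"cover"` (default) flags all `k`
#' bases covered by a repeated window; `"start"` flags only the window start
#' position. The covering policy is the conservative choice for excluding
#' ambiguous bases.
#'
#' @param genome A `tn_genome`.
#' @param k Window size in bp.
#' @param mark Marking policy, `"cover"` or `"start"`.
#' @return An object of class `tn_repeat_mask`: list with `flags` (logical,
#'   one per base), `k`, and `mark`.
#' @export
compute_repeat_mask <- function(genome, k = 21L, mark = c("cover", "start")) {
  mark <- match.arg(mark)
  stopifnot(inherits(genome, "tn_genome"), k >= 1L)
  L <- genome$length
  if (k > L) stop("window size k exceeds genome length")
  n_win <- L - k + 1L
  starts <- seq_len(n_win)
  fwd <- substring(genome$sequence, starts, starts + k - 1L)
  rc <- substring(revcomp(genome$sequence), starts, starts + k - 1L)
  uni <- unique(c(fwd, rc))
  cf <- tabulate(match(fwd, uni), nbins = length(uni))
  cr <- tabulate(match(rc, uni), nbins = length(uni))
  occ <- cf + cr
  rep_start <- starts[occ[match(fwd, uni)] >= 2L]
  flags <- logical(L)
  if (length(rep_start)) {
    if (mark == "start") {
      flags[rep_start] <- TRUE
    } else {
      # delta-encoding of interval coverage, then prefix sum
      d <- integer(L + 1L)
      tb <- tabulate(rep_start, nbins = L + 1L)
      te <- tabulate(rep_start + k, nbins = L + 1L)
      d <- tb - te
      flags <- cumsum(d)[seq_len(L)] > 0L
    }
  }
  structure(list(flags = flags, k = as.integer(k), mark = mark),
            class = "tn_repeat_mask")
}

#' @export
print.tn_repeat_mask <- function(x, ...) {
  cat(sprintf("<tn_repeat_mask> k=%d (%s): %d / %d bases repeated\n",
              x$k, x$mark, sum(x$flags), length(x$flags)))
  invisible(x)
}

#' Fraction of a feature's bases that are repeat-flagged
#'
#' @param start,end 1-based closed interval bounds (vectorized).
#' @param mask A `tn_repeat_mask` (or a bare logical vector).
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
pct_repeated <- function(start, end, mask) {
  flags <- if (inherits(mask, "tn_repeat_mask")) mask$flags else mask
  stopifnot(all(start >= 1L), all(end >= start), all(end <= length(flags)))
  masked_in_ranges(flags, as.integer(start), as.integer(end)) /
    (end - start + 1)
}

#' Export a repeat mask (or segments) as BED
#'
#' BED uses 0-based half-open coordinates; this converts explicitly from the
#' package's 1-based closed convention.
#' @param mask A `tn_repeat_mask`.
#' @param path Output file.
#' @param chrom Chromosome name to write.
#' @export
write_mask_bed <- function(mask, path, chrom = "genome") {
  r <- rle(mask$flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  df <- data.frame(chrom = chrom, start = starts[keep] - 1L, end = ends[keep],
                   name = "repeat")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
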