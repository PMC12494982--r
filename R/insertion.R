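#' Insertion sample container
#'
#' One library x passage x replicate map from 1-based genome position to read
#' count. Positions are stored sorted and must be unique; read counts are
#' positive integers.
#'
#' @param positions Integer genome positions (1-based).
#' @param reads Integer read counts aligned with `positions`.
#' @param library `"P"`, `"T"` or `NA`.
#' @param passage Passage number (0-10) or `NA`.
#' @param replicate Replicate index or `NA`.
#' @return An object of class `tn_sample`.
#' @export
tn_sample <- function(positions, reads, library = NA_character_,
                      passage = NA_integer_, replicate = NA_integer_) {
  positions <- as.integer(positions)
  reads <- as.integer(reads)
  stopifnot(length(positions) == length(reads))
  if (anyDuplicated(positions)) stop("duplicate insertion positions")
  if (length(reads) && any(reads < 1L)) stop("read counts must be >= 1")
  o <- order(positions)
  structure(list(positions = positions[o], reads = reads[o],
                 library = library, passage = as.integer(passage),
                 replicate = as.integer(replicate)),
            class = "tn_sample")
}

#' @export
print.tn_sample <- function(x, ...) {
  cat(sprintf("<tn_sample> %s p%s r%s: %d insertions, %s reads\n",
              x$library, x$passage, x$replicate, length(x$positions),
              format(sum(x$reads), big.mark = ",")))
  invisible(x)
}

#' Read / write a two-column insertion table
#'
#' Tables are TSV with a `position<TAB>reads` header and 1-based positions.
#' Sample metadata (library, passage, replicate) is parsed from filenames of
#' the form `<lib>_p<passage>_r<replicate>.tsv` when present, and can be
#' overridden by arguments.
#'
#' @param path File path.
#' @param genome_length Optional bound for position validation.
#' @param library,passage,replicate Optional metadata overrides.
#' @param sample A `tn_sample` to write.
#' @return `read_insertion_table()` returns a `tn_sample`.
#' @export
read_insertion_table <- function(path, genome_length = NULL,
                                 library = NULL, passage = NULL,
                                 replicate = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^position\treads$", lines[1L]))
    stop("expected header 'position\\treads' in ", path)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  pos <- reads <- integer(length(body))
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) != 2L)
    if (length(bad))
      stop(sprintf("malformed row at line %d of %s", bad[1L] + 1L, path))
    pos <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    reads <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    bad <- which(is.na(pos) | is.na(reads))
    if (length(bad))
      stop(sprintf("non-integer field at line %d of %s", bad[1L] + 1L, path))
    dup <- which(duplicated(pos))
    if (length(dup))
      stop(sprintf("duplicate position %d at line %d of %s",
                   pos[dup[1L]], dup[1L] + 1L, path))
    if (any(pos < 1L))
      stop("position out of range (< 1) in ", path)
    if (!is.null(genome_length) && any(pos > genome_length)) {
      bad <- which(pos > genome_length)[1L]
      stop(sprintf("position out of range at line %d of %s", bad + 1L, path))
    }
  }
  fn <- basename(path)
  m <- regmatches(fn, regexec("^([PT])_p([0-9]+)_r([0-9]+)", fn))[[1L]]
  if (is.null(library)) library <- if (length(m)) m[2L] else NA_character_
  if (is.null(passage)) passage <- if (length(m)) as.integer(m[3L]) else NA_integer_
  if (is.null(replicate)) replicate <- if (length(m)) as.integer(m[4L]) else NA_integer_
  tn_sample(pos, reads, library, passage, replicate)
}

#' @rdname read_insertion_table
#' @export
write_insertion_table <- function(sample, path) {
  con <- file(path, "w")
  writeLines("position\treads", con)
  if (length(sample$positions))
    writeLines(paste(sample$positions, sample$reads, sep = "\t"), con)
  close(con)
  invisible(path)
}

#' Call insertion positions from IR-tagged reads
#'
#' For each read containing the inverted-repeat tag, the post-tag genomic
#' anchor is located in the genome (forward or reverse-complement strand)
#' allowing up to `max_mismatch` substitutions. The genomic base adjacent to
#' the tag is the insertion position; counts accumulate per position.
#' Anchors with two or more equally good placements are discarded as
#' ambiguous (repeats cannot be mapped), and all outcomes are tallied in the
#' run report attached as the `report` attribute.
#'
#' Exact placements are resolved first through a hash of genome k-mers (the
#' genome is treated as circular when `circular = TRUE`, matching
#' [emit_reads()]); only unmatched anchors fall through to the slower
#' mismatch scan.
#'
#' @param reads A FASTQ path or a `DNAStringSet`.
#' @param genome A `tn_genome`.
#' @param ir IR tag sequence.
#' @param max_mismatch Maximum substitutions allowed in the genomic anchor.
#' @param min_anchor Minimum anchor length for a read to be mappable.
#' @param circular Treat the genome as circular.
#' @return A `tn_sample` with attribute `report` (list of tallies).
#' @export
call_insertions <- function(reads, genome, ir = "TACGGACTTTATC",
                            max_mismatch = 1L, min_anchor = 20L,
                            circular = TRUE) {
  if (is.character(reads) && length(reads) == 1L)
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  stopifnot(inherits(genome, "tn_genome"))
  rs <- as.character(reads)
  n_total <- length(rs)
  tagged <- regexpr(ir, rs, fixed = TRUE)
  has_tag <- tagged > 0L
  anchors <- substring(rs[has_tag], tagged[has_tag] + nchar(ir))
  anchors <- anchors[nchar(anchors) >= min_anchor]
  n_tagged <- length(anchors)
  L <- genome$length
  tally <- c(mapped = 0L, ambiguous = 0L, unmapped = 0L)
  hits <- integer(0)
  rcg <- revcomp(genome$sequence)
  for (len in unique(nchar(anchors))) {
    a <- anchors[nchar(anchors) == len]
    ext_f <- if (circular) paste0(genome$sequence,
                                  substr(genome$sequence, 1L, len - 1L))
             else genome$sequence
    ext_r <- if (circular) paste0(rcg, substr(rcg, 1L, len - 1L)) else rcg
    starts <- seq_len(nchar(ext_f) - len + 1L)
    fw <- substring(ext_f, starts, starts + len - 1L)
    rv <- substring(ext_r, starts, starts + len - 1L)
    mf <- match(a, fw)
    mr <- match(a, rv)
    uni <- unique(c(fw, rv))
    occ <- tabulate(match(fw, uni), nbins = length(uni)) +
      tabulate(match(rv, uni), nbins = length(uni))
    n_occ <- occ[match(a, uni)]
    n_occ[is.na(n_occ)] <- 0L
    exact_unique <- !is.na(n_occ) & n_occ == 1L
    pos <- integer(length(a))
    # forward hit at s: insertion = s (mod L for circular wrap); a reverse
    # hit starting at s' in reverse-complement coordinates covers forward
    # interval [L - s' - len + 2, L - s' + 1], and the base adjacent to the
    # tag (first anchor base) is its high end L - s' + 1
    pos[exact_unique & !is.na(mf)] <-
      ((mf[exact_unique & !is.na(mf)] - 1L) %% L) + 1L
    ridx <- exact_unique & is.na(mf) & !is.na(mr)
    pos[ridx] <- L - mr[ridx] + 1L
    hits <- c(hits, pos[exact_unique])
    tally["mapped"] <- tally["mapped"] + sum(exact_unique)
    tally["ambiguous"] <- tally["ambiguous"] + sum(n_occ >= 2L)
    # mismatch fallback for anchors with no exact placement
    for (ai in which(n_occ == 0L)) {
      p <- Biostrings::matchPattern(a[ai], ext_f, max.mismatch = max_mismatch)
      q <- Biostrings::matchPattern(a[ai], ext_r, max.mismatch = max_mismatch)
      cand <- c(BiocGenerics::start(p), BiocGenerics::start(q))
      strand_r <- c(rep(FALSE, length(p)), rep(TRUE, length(q)))
      if (length(cand) == 1L) {
        if (strand_r) hits <- c(hits, L - cand + 1L)
        else hits <- c(hits, ((cand - 1L) %% L) + 1L)
        tally["mapped"] <- tally["mapped"] + 1L
      } else if (length(cand) >= 2L) {
        tally["ambiguous"] <- tally["ambiguous"] + 1L
      } else {
        tally["unmapped"] <- tally["unmapped"] + 1L
      }
    }
  }
  cnt <- table(hits)
  s <- tn_sample(as.integer(names(cnt)), as.integer(cnt))
  n_short <- sum(has_tag) - n_tagged  # tagged but anchor below min_anchor
  attr(s, "report") <- list(reads_total = n_total,
                            tagged = n_tagged,
                            untagged = n_total - sum(has_tag),
                            mapped = unname(tally["mapped"]),
                            ambiguous = unname(tally["ambiguous"]),
                            unmapped = unname(tally["unmapped"]) + n_short)
  s
}

#' Write the insertion-calling run report as JSON
#' @param sample A `tn_sample` from [call_insertions()].
#' @param path Output path.
#' @export
write_call_report <- function(sample, path) {
  rep <- attr(sample, "report")
  if (is.null(rep)) stop("sample carries no call report")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Drop insertions below a read-count floor
#'
#' The standard pipeline disregards single-read insertions
#' (`min_reads = 2`).
#'
#' @param sample A `tn_sample`.
#' @param min_reads Minimum read count to retain a position.
#' @return The filtered `tn_sample`.
#' @export
filter_min_reads <- function(sample, min_reads = 2L) {
  keep <- sample$reads >= min_reads
  tn_sample(sample$positions[keep], sample$reads[keep],
            sample$library, sample$passage, sample$replicate)
}

#' Merge insertion samples with extreme read-count trimming
#'
#' Within each sample, positions whose read counts fall strictly below the
#' `trim` quantile or strictly above the `1 - trim` quantile are dropped
#' (quantile type 7; boundary ties are retained). The merged position set is
#' the union of survivors, and pooled read counts sum over contributing
#' samples. The default `trim = 0.05` drops the top and bottom 5% of
#' insertions by read count before merging.
#'
#' @param samples A list of `tn_sample`.
#' @param trim Trim fraction in \[0, 0.5).
#' @return A `tn_merged`: list with `positions`, `reads`, and `provenance`
#'   (per-sample kept/dropped tallies and the trim used).
#' @export
merge_samples <- function(samples, trim = 0.05) {
  if (inherits(samples, "tn_sample")) samples <- list(samples)
  stopifnot(length(samples) >= 1L)
  if (!is.numeric(trim) || trim < 0 || trim >= 0.5)
    stop("trim must lie in [0, 0.5)")
  env <- new.env()
  pooled <- list()
  prov <- data.frame(library = character(), passage = integer(),
                     replicate = integer(), n_in = integer(),
                     n_dropped = integer())
  for (s in samples) {
    stopifnot(inherits(s, "tn_sample"))
    keep <- rep(TRUE, length(s$reads))
    if (trim > 0 && length(s$reads) > 0L) {
      qlo <- stats::quantile(s$reads, trim, type = 7, names = FALSE)
      qhi <- stats::quantile(s$reads, 1 - trim, type = 7, names = FALSE)
      keep <- s$reads >= qlo & s$reads <= qhi
    }
    prov <- rbind(prov, data.frame(library = s$library, passage = s$passage,
                                   replicate = s$replicate,
                                   n_in = length(s$reads),
                                   n_dropped = sum(!keep)))
    pooled[[length(pooled) + 1L]] <-
      data.frame(pos = s$positions[keep], reads = s$reads[keep])
  }
  all <- do.call(rbind, pooled)
  agg <- rowsum(all$reads, all$pos)
  pos <- as.integer(rownames(agg))
  o <- order(pos)
  structure(list(positions = pos[o], reads = as.integer(agg[o, 1L]),
                 provenance = list(samples = prov, trim = trim)),
            class = "tn_merged")
}

#' @export
print.tn_merged <- function(x, ...) {
  cat(sprintf("<tn_merged> %d samples, trim %.2f: %s positions, %s reads\n",
              nrow(x$provenance$samples), x$provenance$trim,
              format(length(x$positions), big.mark = ","),
              format(sum(as.numeric(x$reads)), big.mark = ",")))
  invisible(x)
}
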