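#' Feature table constructor / validator
#'
#' Features are stored as a plain data.frame with one row per feature and
#' columns: `id`, `ftype`, `start`, `end`, `strand`, `operon_id`, `cog`,
#' `gold_ne`, plus optional bookkeeping columns (`true_class` from the
#' simulator, `pct_repeated` once a mask is applied). Coordinates are 1-based
#' closed intervals; strand is one of `+`, `-`, `.`.
#'
#' @param df A data.frame with at least `id`, `ftype`, `start`, `end`.
#' @param genome_length Optional genome length for bounds checking.
#' @return The validated data.frame with class `tn_features` prepended.
#' @export
tn_features <- function(df, genome_length = NULL) {
  stopifnot(is.data.frame(df))
  required <- c("id", "ftype", "start", "end")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  if (!"strand" %in% names(df)) df$strand <- "."
  if (!"operon_id" %in% names(df)) df$operon_id <- NA_character_
  if (!"cog" %in% names(df)) df$cog <- NA_character_
  if (!"gold_ne" %in% names(df)) df$gold_ne <- FALSE
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyDuplicated(df$id)) stop("feature ids must be unique")
  if (any(df$start < 1L) || any(df$end < df$start))
    stop("invalid feature coordinates (need 1 <= start <= end)")
  if (!is.null(genome_length) && any(df$end > genome_length))
    stop("feature end exceeds genome length")
  if (!all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  class(df) <- unique(c("tn_features", class(df)))
  df
}

FEATURE_TYPES <- c("gene", "tRNA", "rRNA", "ncRNA", "promoter", "TSS", "TTS",
                   "UTR5", "UTR3", "iGiO", "RBS", "binding_site", "noann",
                   "noexp")

#' Annotate features with their repeated-sequence fraction
#'
#' @param features A `tn_features` table.
#' @param mask A `tn_repeat_mask`.
#' @return The table with a `pct_repeated` column filled in.
#' @export
annotate_pct_repeated <- function(features, mask) {
  features$pct_repeated <- pct_repeated(features$start, features$end, mask)
  features
}

#' Derive regulatory elements from genes, TSS and TTS
#'
#' Builds 5' UTRs (nearest upstream TSS to the gene start), 3' UTRs (gene end
#' to the nearest downstream TTS within `tts_search` bp, else a fixed
#' `utr3_fallback` bp stretch), and inter-genic-intra-operon (iGiO) regions
#' (gaps between consecutive non-overlapping genes sharing an operon). All
#' derivations are strand-aware: upstream of a minus-strand gene means higher
#' coordinates.
#'
#' @param features A `tn_features` table containing genes and rows of ftype
#'   `TSS` / `TTS` (point features, `start == end`).
#' @param genome_length Genome length (bp) for clipping.
#' @param tts_search Search range downstream of a gene for a TTS (bp).
#' @param utr3_fallback Fixed 3' UTR length when no TTS is found (bp).
#' @return The input table with derived UTR5/UTR3/iGiO rows appended.
#' @export
derive_regulatory_elements <- function(features, genome_length,
                                       tts_search = 500L,
                                       utr3_fallback = 150L) {
  genes <- features[features$ftype == "gene", , drop = FALSE]
  tss <- features[features$ftype == "TSS", , drop = FALSE]
  tts <- features[features$ftype == "TTS", , drop = FALSE]
  new <- list()
  add <- function(id, ftype, start, end, strand, operon = NA_character_) {
    start <- max(1L, as.integer(start)); end <- min(genome_length, as.integer(end))
    if (start > end) return()
    new[[length(new) + 1L]] <<- data.frame(
      id = id, ftype = ftype, start = start, end = end, strand = strand,
      operon_id = operon, cog = NA_character_, gold_ne = FALSE,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    st <- g$strand
    same <- if (nrow(tss)) tss[tss$strand == st | tss$strand == ".", ] else tss
    if (st == "-") {
      up <- same$start[same$start > g$end]
      if (length(up)) {
        p <- min(up)
        if (p > g$end) add(paste0("utr5_", g$id), "UTR5", g$end + 1L, p, st)
        else warning("TSS downstream of gene start for ", g$id, "; skipped")
      }
      dn <- if (nrow(tts)) tts$start[(tts$strand == st | tts$strand == ".") &
                                     tts$start < g$start &
                                     tts$start >= g$start - tts_search] else integer()
      if (length(dn)) add(paste0("utr3_", g$id), "UTR3", max(dn), g$start - 1L, st)
      else add(paste0("utr3_", g$id), "UTR3", g$start - utr3_fallback, g$start - 1L, st)
    } else {
      up <- same$start[same$start < g$start]
      if (length(up)) {
        p <- max(up)
        if (p < g$start) add(paste0("utr5_", g$id), "UTR5", p, g$start - 1L, st)
        else warning("TSS downstream of gene start for ", g$id, "; skipped")
      }
      dn <- if (nrow(tts)) tts$start[(tts$strand == st | tts$strand == ".") &
                                     tts$start > g$end &
                                     tts$start <= g$end + tts_search] else integer()
      if (length(dn)) add(paste0("utr3_", g$id), "UTR3", g$end + 1L, min(dn), st)
      else add(paste0("utr3_", g$id), "UTR3", g$end + 1L, g$end + utr3_fallback, st)
    }
  }
  # iGiO: gaps between consecutive non-overlapping genes in the same operon
  og <- genes[!is.na(genes$operon_id), , drop = FALSE]
  og <- og[order(og$start), , drop = FALSE]
  if (nrow(og) >= 2L) {
    for (i in seq_len(nrow(og) - 1L)) {
      a <- og[i, ]; b <- og[i + 1L, ]
      if (identical(a$operon_id, b$operon_id) && b$start > a$end + 1L)
        add(paste0("igio_", a$id, "_", b$id), "iGiO", a$end + 1L, b$start - 1L,
            a$strand, a$operon_id)
    }
  }
  if (length(new)) {
    app <- do.call(rbind, new)
    app <- app[!app$id %in% features$id, , drop = FALSE]
    for (col in setdiff(names(features), names(app))) app[[col]] <- NA
    features <- tn_features(rbind(features, app[, names(features)]),
                            genome_length)
  }
  features
}

#' Read / write annotation as GFF3 plus a TSV sidecar
#'
#' The GFF3 carries coordinates, type and strand (1-based closed intervals);
#' simulator-specific columns (`true_class`, `gold_ne`, `cog`, `operon_id`)
#' travel in a tab-separated sidecar keyed by feature id so the GFF3 stays
#' standard.
#'
#' @param features A `tn_features` table.
#' @param path GFF3 path; the sidecar is written next to it as
#'   `<path>.meta.tsv`.
#' @param genome_id Sequence name for column 1.
#' @return `read_annotation()` returns a `tn_features` table.
#' @export
write_annotation <- function(features, path, genome_id = "genome") {
  attrs <- paste0("ID=", features$id)
  gff <- data.frame(seqid = genome_id, source = "tnseqr",
                    type = features$ftype, start = features$start,
                    end = features$end, score = ".",
                    strand = features$strand, phase = ".",
                    attributes = attrs, stringsAsFactors = FALSE)
  con <- file(path, "w")
  writeLines("##gff-version 3", con)
  utils::write.table(gff, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  meta_cols <- intersect(c("id", "operon_id", "cog", "gold_ne", "true_class",
                           "pct_repeated"), names(features))
  utils::write.table(features[, meta_cols, drop = FALSE],
                     paste0(path, ".meta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  gff <- utils::read.table(text = lines, sep = "\t", quote = "",
                           stringsAsFactors = FALSE,
                           col.names = c("seqid", "source", "type", "start",
                                         "end", "score", "strand", "phase",
                                         "attributes"))
  id <- sub("^ID=([^;]+).*$", "\\1", gff$attributes)
  df <- data.frame(id = id, ftype = gff$type, start = gff$start,
                   end = gff$end, strand = gff$strand,
                   stringsAsFactors = FALSE)
  side <- paste0(path, ".meta.tsv")
  if (file.exists(side)) {
    meta <- utils::read.table(side, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    df <- merge(df, meta, by = "id", sort = FALSE)
    df <- df[match(id, df$id), , drop = FALSE]
    rownames(df) <- NULL
  }
  tn_features(df)
}
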