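# Annotation-independent segmentation of the genome into essential (E) and
# non-essential (NE) domains by a calibrated sliding window.

#' Per-window linear densities over the genome
#'
#' Slides a `w`-bp window with step 1 and computes the insertion linear
#' density of each window on its non-repeated bases. Windows with no
#' non-repeated base are uninformative (they carry no mapping evidence) and
#' get `NA` density.
#'
#' @param x A `tn_sample` or `tn_merged`.
#' @param genome_length Genome length in bp.
#' @param mask Optional `tn_repeat_mask`.
#' @param w Window size (bp).
#' @return List: `start` (window starts), `ld`, `informative` (logical),
#'   `w`.
#' @export
window_ld_track <- function(x, genome_length, mask = NULL, w = 31L) {
  if (genome_length < w) stop("genome shorter than window")
  n_win <- genome_length - w + 1L
  ins <- integer(genome_length)
  pos <- x$positions
  flags <- if (is.null(mask)) rep(FALSE, genome_length)
           else if (inherits(mask, "tn_repeat_mask")) mask$flags else mask
  pos <- pos[!flags[pos]]
  ins[pos] <- 1L
  cins <- c(0L, cumsum(ins))
  cmask <- c(0L, cumsum(!flags))
  starts <- seq_len(n_win)
  n_ins <- cins[starts + w] - cins[starts]
  n_eff <- cmask[starts + w] - cmask[starts]
  ld <- ifelse(n_eff > 0L, n_ins / n_eff, NA_real_)
  list(start = starts, ld = ld, informative = n_eff > 0L, w = as.integer(w))
}

# Binary E/NE classification of window densities. A 2-component mixture is
# fitted and reduced to the LD value where the two component densities cross
# (between the component means): windows above the cutoff are NE. Reducing
# the classifier to a threshold keeps window calls monotone in the data --
# adding insertions can only move windows from E to NE for a fixed cutoff.
# Degenerate data fall back to a 0.5 LD cutoff.
window_ld_cutoff <- function(ld, seed = NULL, max_fit_n = 50000L) {
  vals <- ld[!is.na(ld)]
  if (!length(vals)) return(0.5)
  if (length(unique(vals)) < 2L || stats::sd(vals) == 0) return(0.5)
  fit_vals <- if (length(vals) > max_fit_n)
    with_seed(if (is.null(seed)) 0L else seed,
              sample(vals, max_fit_n)) else vals
  fit <- tryCatch(
    suppressWarnings(fit_mixture(fit_vals, k_candidates = 2L, seed = seed)),
    error = function(e) NULL)
  f <- if (!is.null(fit)) fit$fits[["2"]] else NULL
  if (is.null(f) || length(f$means) != 2L) return(0.5)
  ord <- order(f$means)
  w <- f$weights[ord]; mu <- f$means[ord]; s <- sqrt(f$variances[ord])
  if (mu[2L] - mu[1L] < 1e-12) return(mu[1L])
  score <- function(x)
    (stats::dnorm(x, mu[1L], s[1L], log = TRUE) + log(w[1L])) -
    (stats::dnorm(x, mu[2L], s[2L], log = TRUE) + log(w[2L]))
  lo <- mu[1L]; hi <- mu[2L]
  if (score(lo) > 0 && score(hi) < 0)
    stats::uniroot(score, c(lo, hi))$root
  else mean(mu)
}

classify_window_ld <- function(ld, seed = NULL, cutoff = NULL) {
  if (is.null(cutoff)) cutoff <- window_ld_cutoff(ld, seed = seed)
  labels <- rep(NA_character_, length(ld))
  ok <- !is.na(ld)
  labels[ok] <- ifelse(ld[ok] > cutoff, "NE", "E")
  attr(labels, "cutoff") <- cutoff
  labels
}

#' Calibrate the sliding-window size on labeled window pools
#'
#' For each candidate window size, samples windows lying fully inside known
#' essential and non-essential genes, pools their linear densities, fits an
#' unsupervised two-component mixture, classifies every window, and records
#' the probability of wrongly assigning the NE category to a window sampled
#' from an E gene. The chosen size is the smallest one with error below
#' `tol` (default 5%).
#'
#' @param x A `tn_sample` or `tn_merged`.
#' @param e_genes,ne_genes Feature tables of genes with known essentiality.
#' @param genome_length Genome length.
#' @param mask Optional repeat mask.
#' @param sizes Candidate window sizes (bp).
#' @param n_windows Windows sampled per class per size.
#' @param tol Error tolerance.
#' @param seed RNG seed.
#' @param on_fail `"error"` (default) or `"na"` when no size is admissible.
#' @return List: `curve` (data.frame size, error), `chosen_w`.
#' @export
calibrate_window <- function(x, e_genes, ne_genes, genome_length,
                             mask = NULL, sizes = c(3L, 7L, 15L, 31L, 63L,
                                                    101L, 149L),
                             n_windows = 1000L, tol = 0.05, seed = NULL,
                             on_fail = c("error", "na")) {
  on_fail <- match.arg(on_fail)
  sample_windows <- function(genes, w) {
    spans <- genes[genes$end - genes$start + 1L >= w, , drop = FALSE]
    if (!nrow(spans)) return(integer(0))
    gi <- sample.int(nrow(spans), n_windows, replace = TRUE)
    off <- floor(stats::runif(n_windows) *
                   (spans$end[gi] - spans$start[gi] - w + 2L))
    spans$start[gi] + as.integer(off)
  }
  window_ld_at <- function(starts, w) {
    ins <- integer(genome_length)
    flags <- if (is.null(mask)) rep(FALSE, genome_length)
             else if (inherits(mask, "tn_repeat_mask")) mask$flags else mask
    pos <- x$positions[!flags[x$positions]]
    ins[pos] <- 1L
    cins <- c(0L, cumsum(ins)); cm <- c(0L, cumsum(!flags))
    n_ins <- cins[starts + w] - cins[starts]
    n_eff <- cm[starts + w] - cm[starts]
    ifelse(n_eff > 0L, n_ins / n_eff, NA_real_)
  }
  with_seed(seed, {
    err <- rep(NA_real_, length(sizes))
    for (i in seq_along(sizes)) {
      w <- sizes[i]
      se <- sample_windows(e_genes, w)
      sn <- sample_windows(ne_genes, w)
      if (length(se) < 10L || length(sn) < 10L)
        stop("window pools too small at size ", w)
      ld_e <- window_ld_at(se, w)
      ld_n <- window_ld_at(sn, w)
      labels <- classify_window_ld(c(ld_e, ld_n))
      lab_e <- labels[seq_along(ld_e)]
      err[i] <- mean(lab_e == "NE", na.rm = TRUE)
    }
    curve <- data.frame(size = sizes, error = err)
    adm <- which(!is.na(err) & err < tol)
    if (!length(adm)) {
      if (on_fail == "error")
        stop("no window size reaches the error tolerance ", tol)
      return(list(curve = curve, chosen_w = NA_integer_))
    }
    list(curve = curve, chosen_w = sizes[min(adm)])
  })
}

#' Segment the genome into E and NE domains
#'
#' Classifies every informative `w`-bp window as E or NE with an
#' unsupervised two-component mixture over window linear densities; every
#' base covered by at least one NE-classified window belongs to an NE
#' domain, all remaining bases are labeled E, and adjacent same-label runs
#' merge into maximal segments. The result tiles the genome exactly.
#'
#' @param x A `tn_sample` or `tn_merged`.
#' @param genome_length Genome length (bp), or a `tn_genome`.
#' @param mask Optional `tn_repeat_mask`.
#' @param w Window size (bp), typically calibrated with
#'   [calibrate_window()].
#' @param coverage `"any"` (a base is NE if any covering window is NE;
#'   default, conservative for declaring essentiality) or `"majority"`.
#' @param seed RNG seed for the mixture fit.
#' @param cutoff Optional fixed window-LD cutoff; when `NULL` (default) the
#'   classifier is refit on this dataset. Supplying the cutoff of a
#'   previous segmentation (the `cutoff` attribute of its result) reuses
#'   that classifier, under which adding insertions can only shrink E
#'   territory.
#' @return A data.frame of segments: `start`, `end`, `label`, `length`,
#'   `pct_repeated`, with the window classifier's LD `cutoff` as an
#'   attribute.
#' @export
segment_genome <- function(x, genome_length, mask = NULL, w = 31L,
                           coverage = c("any", "majority"), seed = NULL,
                           cutoff = NULL) {
  coverage <- match.arg(coverage)
  if (inherits(genome_length, "tn_genome"))
    genome_length <- genome_length$length
  track <- window_ld_track(x, genome_length, mask, w)
  labels <- classify_window_ld(track$ld, seed = seed, cutoff = cutoff)
  ne_start <- track$start[!is.na(labels) & labels == "NE"]
  L <- genome_length
  cov <- integer(L)
  if (length(ne_start)) {
    d <- tabulate(ne_start, nbins = L + 1L) -
      tabulate(ne_start + w, nbins = L + 1L)
    cov <- cumsum(d)[seq_len(L)]
  }
  if (coverage == "any") {
    is_ne <- cov > 0L
  } else {
    tot_start <- track$start[!is.na(labels)]
    tot <- integer(L)
    if (length(tot_start)) {
      d <- tabulate(tot_start, nbins = L + 1L) -
        tabulate(tot_start + w, nbins = L + 1L)
      tot <- cumsum(d)[seq_len(L)]
    }
    is_ne <- tot > 0L & cov * 2L > tot
  }
  r <- rle(is_ne)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts, end = ends,
                    label = ifelse(r$values, "NE", "E"),
                    length = r$lengths, stringsAsFactors = FALSE)
  seg$pct_repeated <- if (is.null(mask)) 0 else
    pct_repeated(seg$start, seg$end, mask)
  attr(seg, "cutoff") <- attr(labels, "cutoff")
  seg
}

#' Filter reported E segments
#'
#' Reporting keeps only E segments covering at least `min_len` bp with less
#' than `max_repeat` of the segment repeated; NE segments pass through. The
#' unfiltered segmentation (which tiles the genome) should be retained for
#' coordinate bookkeeping.
#'
#' @param segments Segment table from [segment_genome()].
#' @param min_len Minimum E segment length (bp).
#' @param max_repeat Maximum repeated fraction for E segments.
#' @return The reported subset.
#' @export
filter_segments <- function(segments, min_len = 5L, max_repeat = 0.10) {
  keep <- segments$label == "NE" |
    (segments$length >= min_len & segments$pct_repeated < max_repeat)
  segments[keep, , drop = FALSE]
}

#' Map segments onto an annotation
#'
#' Interval-intersection bookkeeping between segments and features: per
#' feature, the fraction of its span covered by E segments and the number of
#' distinct E segments it touches; per segment, the overlapping feature ids
#' (or "non-annotated").
#'
#' @param segments Segment table.
#' @param features A `tn_features` table.
#' @return List of data.frames `per_feature` (`feature_id`, `pct_essential`,
#'   `n_e_segments`) and `per_segment` (`start`, `end`, `label`,
#'   `features`).
#' @export
map_segments <- function(segments, features) {
  segr <- IRanges::IRanges(segments$start, segments$end)
  fr <- IRanges::IRanges(features$start, features$end)
  ov <- IRanges::findOverlaps(fr, segr)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  inter <- pmin(features$end[qh], segments$end[sh]) -
    pmax(features$start[qh], segments$start[sh]) + 1L
  is_e <- segments$label[sh] == "E"
  e_bp <- tapply(inter[is_e], qh[is_e], sum)
  e_n <- tapply(inter[is_e], qh[is_e], length)
  pct <- rep(0, nrow(features))
  nseg <- rep(0L, nrow(features))
  idx <- as.integer(names(e_bp))
  pct[idx] <- as.numeric(e_bp) / (features$end[idx] - features$start[idx] + 1L)
  nseg[idx] <- as.integer(e_n)
  per_feature <- data.frame(feature_id = features$id, pct_essential = pct,
                            n_e_segments = nseg, stringsAsFactors = FALSE)
  feat_by_seg <- tapply(features$id[qh], sh, paste, collapse = ",")
  per_segment <- segments
  per_segment$features <- "non-annotated"
  sidx <- as.integer(names(feat_by_seg))
  per_segment$features[sidx] <- as.character(feat_by_seg)
  list(per_feature = per_feature, per_segment = per_segment)
}

#' Export segments as BED (0-based half-open)
#' @param segments Segment table.
#' @param path Output path.
#' @param chrom Chromosome name.
#' @export
write_segments_bed <- function(segments, path, chrom = "genome") {
  df <- data.frame(chrom = chrom, start = segments$start - 1L,
                   end = segments$end, name = segments$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
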