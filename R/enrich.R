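# Statistics for insertions positively selected over serial passages:
# valid-position bookkeeping, TMM count normalization, per-position and
# whole-gene one-tailed tests, annotation categories, COG enrichment, and
# the binding-site accessibility comparison.

#' Positions conserved across first and last passage in both replicates
#'
#' The enrichment analysis only considers insertions detected in passage 1
#' and passage 10 in both replicates of a library: the intersection of the
#' four position sets.
#'
#' @param p1_rep1,p1_rep2,p10_rep1,p10_rep2 `tn_sample` objects.
#' @return Sorted integer vector of valid positions.
#' @export
valid_positions <- function(p1_rep1, p1_rep2, p10_rep1, p10_rep2) {
  sets <- list(p1_rep1$positions, p1_rep2$positions,
               p10_rep1$positions, p10_rep2$positions)
  if (any(lengths(sets) == 0L)) {
    warning("empty sample; no valid positions")
    return(integer(0))
  }
  sort(Reduce(intersect, sets))
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Computes per-sample TMM factors against a reference column: log2 ratios
#' (M) of library-size-scaled counts are trimmed (default 30% each tail),
#' as are extreme average abundances (A, default 5% each tail), and the
#' mean of the surviving M values is exponentiated. The mean is unweighted:
#' M and A depend only on count proportions, so the factors are exactly
#' scale-equivariant (multiplying a sample's counts by `c` multiplies its
#' factor by `c`), which the delta-method precision weighting of some TMM
#' implementations sacrifices.
#' The returned factor includes the library-size ratio, so dividing a
#' sample's counts by its factor places them on the reference scale: a
#' duplicate of the reference gets factor 1, and a sample with every count
#' doubled gets factor 2.
#'
#' @param counts Numeric matrix, positions x samples (shared positions).
#' @param ref Reference column index or name (default 1).
#' @param trim_m,trim_a Trim fractions for M and A.
#' @return Named numeric vector of factors, one per column.
#' @export
tmm_factors <- function(counts, ref = 1L, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (is.character(ref)) ref <- match(ref, colnames(counts))
  libsize <- colSums(counts)
  yr <- counts[, ref]
  factors <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    yj <- counts[, j]
    keep <- yj > 0 & yr > 0
    if (!any(keep)) stop("no co-detected positions with the reference")
    pj <- yj[keep] / libsize[j]
    pr <- yr[keep] / libsize[ref]
    M <- log2(pj / pr)
    A <- (log2(pj) + log2(pr)) / 2
    n <- length(M)
    if (n > 1L) {
      loM <- stats::quantile(M, trim_m, type = 7, names = FALSE)
      hiM <- stats::quantile(M, 1 - trim_m, type = 7, names = FALSE)
      loA <- stats::quantile(A, trim_a, type = 7, names = FALSE)
      hiA <- stats::quantile(A, 1 - trim_a, type = 7, names = FALSE)
      sel <- M >= loM & M <= hiM & A >= loA & A <= hiA
      if (!any(sel)) sel <- rep(TRUE, n)
    } else sel <- TRUE
    tmm <- mean(M[sel])
    factors[j] <- 2^tmm * libsize[j] / libsize[ref]
  }
  names(factors) <- colnames(counts)
  factors
}

#' Per-position enrichment between first and last passage
#'
#' Tests each valid position for a read-count increase from passage 1 to
#' passage 10 on TMM-normalized counts: `log2fc = log2(mean P10 / mean P1)`,
#' a one-tailed two-sample t-test for increase (selection acts upward by
#' construction of the experiment), and Bonferroni correction over the
#' number of positions tested. Positions with zero passage-1 mean cannot
#' form a ratio and are excluded from testing but reported with
#' `tested = FALSE`.
#'
#' @param counts_p1 Matrix positions x replicates of normalized passage-1
#'   counts (rownames are positions).
#' @param counts_p10 Matching matrix for passage 10.
#' @param alpha Significance level on adjusted p-values.
#' @return Data.frame: `position`, `log2fc`, `p_raw`, `p_adj`, `enriched`,
#'   `tested`.
#' @export
position_enrichment <- function(counts_p1, counts_p10, alpha = 0.05) {
  stopifnot(nrow(counts_p1) == nrow(counts_p10))
  pos <- rownames(counts_p1)
  if (is.null(pos)) pos <- as.character(seq_len(nrow(counts_p1)))
  m1 <- rowMeans(counts_p1)
  m10 <- rowMeans(counts_p10)
  tested <- m1 > 0
  log2fc <- ifelse(tested, log2(ifelse(m10 > 0, m10, NA) / m1), NA_real_)
  log2fc[tested & m10 == 0] <- -Inf
  p_raw <- rep(NA_real_, length(m1))
  for (i in which(tested)) {
    a <- counts_p10[i, ]; b <- counts_p1[i, ]
    if (stats::sd(c(a, b)) == 0) { p_raw[i] <- 1; next }
    p_raw[i] <- tryCatch(
      stats::t.test(a, b, alternative = "greater")$p.value,
      error = function(e) NA_real_)
  }
  m <- sum(tested)
  p_adj <- pmin(1, p_raw * m)
  data.frame(position = as.integer(pos), log2fc = log2fc,
             p_raw = p_raw, p_adj = p_adj,
             enriched = !is.na(p_adj) & p_adj < alpha & log2fc > 0,
             tested = tested, stringsAsFactors = FALSE)
}

POSITION_CATEGORIES <- c("overlap E/F1 gene", "overlap F2/NE gene",
                         "upstream E/F1 gene", "upstream F2/NE gene",
                         "overlap UTR5", "upstream UTR5", "overlap iGiO",
                         "overlap non-transcribed", "between two gene ends",
                         "not classified")

#' Categorize positions against the annotation
#'
#' Maps each position to every matching annotation category: overlap with
#' E/F1 or F2/NE genes, strand-aware upstream windows (default 250 bp) of
#' genes and 5' UTRs, overlap with 5' UTRs, iGiO regions or non-transcribed
#' regions (`noexp`/`noann` features), location between the 3' ends of two
#' convergent genes, and "not classified" when nothing matches.
#'
#' @param positions Integer positions.
#' @param features A `tn_features` table.
#' @param gene_calls Data.frame with `feature_id`, `category` for genes.
#' @param upstream_window Upstream window in bp.
#' @return Data.frame `position`, `categories` (comma-separated).
#' @export
categorize_positions <- function(positions, features, gene_calls,
                                 upstream_window = 250L) {
  genes <- features[features$ftype %in% c("gene", "tRNA", "rRNA"), ,
                    drop = FALSE]
  cat_of <- gene_calls$category[match(genes$id, gene_calls$feature_id)]
  ef <- !is.na(cat_of) & cat_of %in% c("E", "F1")
  fn <- !is.na(cat_of) & cat_of %in% c("F2", "NE")
  utr5 <- features[features$ftype == "UTR5", , drop = FALSE]
  igio <- features[features$ftype == "iGiO", , drop = FALSE]
  notx <- features[features$ftype %in% c("noexp", "noann"), , drop = FALSE]
  in_any <- function(p, df) {
    if (!nrow(df)) return(rep(FALSE, length(p)))
    ir <- IRanges::IRanges(df$start, df$end)
    IRanges::countOverlaps(IRanges::IRanges(p, p), ir) > 0L
  }
  upstream_of <- function(p, df) {
    if (!nrow(df)) return(rep(FALSE, length(p)))
    us <- ifelse(df$strand == "-", df$end + 1L,
                 pmax(1L, df$start - upstream_window))
    ue <- ifelse(df$strand == "-", df$end + upstream_window, df$start - 1L)
    ok <- us <= ue
    if (!any(ok)) return(rep(FALSE, length(p)))
    ir <- IRanges::IRanges(us[ok], ue[ok])
    IRanges::countOverlaps(IRanges::IRanges(p, p), ir) > 0L
  }
  # between two gene ends: gap between consecutive convergent genes (+ then -)
  go <- genes[order(genes$start), , drop = FALSE]
  conv <- list()
  if (nrow(go) >= 2L) for (i in seq_len(nrow(go) - 1L)) {
    if (go$strand[i] == "+" && go$strand[i + 1L] == "-" &&
        go$start[i + 1L] > go$end[i] + 1L)
      conv[[length(conv) + 1L]] <- c(go$end[i] + 1L, go$start[i + 1L] - 1L)
  }
  conv_df <- if (length(conv)) {
    m <- do.call(rbind, conv)
    data.frame(start = m[, 1L], end = m[, 2L])
  } else data.frame(start = integer(), end = integer())
  flags <- cbind(
    "overlap E/F1 gene" = in_any(positions, genes[ef, , drop = FALSE]),
    "overlap F2/NE gene" = in_any(positions, genes[fn, , drop = FALSE]),
    "upstream E/F1 gene" = upstream_of(positions, genes[ef, , drop = FALSE]),
    "upstream F2/NE gene" = upstream_of(positions, genes[fn, , drop = FALSE]),
    "overlap UTR5" = in_any(positions, utr5),
    "upstream UTR5" = upstream_of(positions, utr5),
    "overlap iGiO" = in_any(positions, igio),
    "overlap non-transcribed" = in_any(positions, notx),
    "between two gene ends" = in_any(positions, conv_df))
  cats <- apply(flags, 1L, function(r)
    if (!any(r)) "not classified" else paste(colnames(flags)[r],
                                             collapse = ","))
  data.frame(position = positions, categories = cats,
             stringsAsFactors = FALSE)
}

#' Whole-gene read enrichment with hottest-insertion subtraction
#'
#' Tests whether a gene's coding sequence shows a read enrichment from
#' passage 1 to passage 10 that is not driven by a few hot insertions: the
#' `top_k_subtract` insertions with the highest passage-10 reads are
#' removed, then a one-tailed paired t-test compares per-insertion
#' normalized reads (P10 vs P1) over the remaining shared insertions.
#'
#' @param gene One row of a feature table.
#' @param reads_p1,reads_p10 Named numeric vectors: normalized mean reads
#'   per insertion position (names are positions) for each passage.
#' @param top_k_subtract Number of hottest passage-10 insertions removed.
#' @param alpha Significance level.
#' @return List: `verdict` ("enriched", "not enriched", "not evaluable"),
#'   `p_value`, `n_insertions_tested`.
#' @export
whole_gene_enrichment <- function(gene, reads_p1, reads_p10,
                                  top_k_subtract = 3L, alpha = 0.05) {
  in_gene <- function(v) {
    p <- as.integer(names(v))
    v[p >= gene$start & p <= gene$end]
  }
  r1 <- in_gene(reads_p1)
  r10 <- in_gene(reads_p10)
  shared <- intersect(names(r1), names(r10))
  if (length(r10) < top_k_subtract + 2L || length(shared) < top_k_subtract + 2L)
    return(list(verdict = "not evaluable", p_value = NA_real_,
                n_insertions_tested = 0L))
  hot <- names(sort(r10, decreasing = TRUE))[seq_len(top_k_subtract)]
  keep <- setdiff(shared, hot)
  if (length(keep) < 2L)
    return(list(verdict = "not evaluable", p_value = NA_real_,
                n_insertions_tested = 0L))
  a <- r10[keep]; b <- r1[keep]
  if (stats::sd(a - b) == 0) {
    p <- if (mean(a) > mean(b)) 0 else 1
  } else {
    p <- stats::t.test(a, b, paired = TRUE,
                       alternative = "greater")$p.value
  }
  list(verdict = if (!is.na(p) && p < alpha) "enriched" else "not enriched",
       p_value = p, n_insertions_tested = length(keep))
}

#' COG category enrichment by hypergeometric test
#'
#' For each COG letter, counts hit genes against the background and computes
#' the upper-tail hypergeometric probability of drawing at least that many
#' category members, with Benjamini-Hochberg adjustment across letters.
#'
#' @param hit_genes Character ids of genes affected by enriched insertions.
#' @param background Data.frame with `id` and `cog` for all candidate genes.
#' @return Data.frame: `cog`, `n_hit`, `n_category`, `n_background`,
#'   `n_hits_total`, `p_hyper`, `q_bh`.
#' @export
cog_enrichment <- function(hit_genes, background) {
  if (!nrow(background)) stop("empty background")
  if (!all(hit_genes %in% background$id))
    stop("hit genes must be a subset of the background")
  bg <- background[!is.na(background$cog), , drop = FALSE]
  N <- nrow(bg)
  n_draw <- sum(hit_genes %in% bg$id)
  cogs <- sort(unique(bg$cog))
  out <- lapply(cogs, function(cg) {
    K <- sum(bg$cog == cg)
    x <- sum(bg$cog == cg & bg$id %in% hit_genes)
    p <- stats::phyper(x - 1L, K, N - K, n_draw, lower.tail = FALSE)
    data.frame(cog = cg, n_hit = x, n_category = K, n_background = N,
               n_hits_total = n_draw, p_hyper = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q_bh <- stats::p.adjust(out$p_hyper, method = "BH")
  out
}

#' Transposon accessibility at protein-bound sites
#'
#' Compares insertion metrics inside DNA-binding sites with same-length
#' upstream and downstream flanks: per site, linear density and total reads
#' for the site and each flank; across sites, a one-tailed paired t-test of
#' site values against the mean of the two flanks (site < flanks). Sites
#' whose flanks fall off the genome are skipped.
#'
#' @param sites Data.frame with `start`, `end` (and optionally `id`).
#' @param x A `tn_sample` or `tn_merged`.
#' @param genome_length Genome length.
#' @param mask Optional repeat mask.
#' @return List: `per_site` data.frame and `p_ld`, `p_reads` (NA with a
#'   single site, where the paired test is undefined).
#' @export
accessibility_test <- function(sites, x, genome_length, mask = NULL) {
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    len <- s$end - s$start + 1L
    us <- s$start - len; ue <- s$start - 1L
    ds <- s$end + 1L; de <- s$end + len
    if (us < 1L || de > genome_length) next
    f <- data.frame(id = c("site", "up", "down"), ftype = "binding_site",
                    start = c(s$start, us, ds), end = c(s$end, ue, de),
                    stringsAsFactors = FALSE)
    m <- linear_density(x, f, mask = mask, exclude_repeats = !is.null(mask))
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = if ("id" %in% names(sites)) s$id else as.character(i),
      start = s$start, end = s$end,
      ld_site = m$ld[1L], ld_flanks = mean(m$ld[2:3]),
      reads_site = m$total_reads[1L],
      reads_flanks = mean(m$total_reads[2:3]),
      stringsAsFactors = FALSE)
  }
  per_site <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(), start = integer(), end = integer(),
               ld_site = numeric(), ld_flanks = numeric(),
               reads_site = numeric(), reads_flanks = numeric())
  one_tail <- function(a, b) {
    if (nrow(per_site) < 2L) return(NA_real_)
    if (stats::sd(a - b) == 0) return(if (mean(a) < mean(b)) 0 else 1)
    stats::t.test(a, b, paired = TRUE, alternative = "less")$p.value
  }
  list(per_site = per_site,
       p_ld = one_tail(per_site$ld_site, per_site$ld_flanks),
       p_reads = one_tail(per_site$reads_site, per_site$reads_flanks))
}
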