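#' Build NE-normalized decay trajectories across passages
#'
#' For each passage, computes a per-feature metric (linear density by
#' default, or insertion-mapped reads) and divides it by the mean of the
#' gold non-essential set in that same passage, so trajectories are
#' comparable across samples with different insertion coverage. Missing
#' passages are simply absent from the grid, never imputed.
#'
#' @param samples_by_passage Named list: passage number (as name) to
#'   `tn_sample` / `tn_merged`.
#' @param features Feature table; trajectories are built for all rows.
#' @param gold Ids (or logical over rows) of the gold NE set.
#' @param mask Optional `tn_repeat_mask` for repeat-excluded LD.
#' @param metric `"ld"` or `"reads"`.
#' @return A `tn_profiles`: list with `values` (feature x passage matrix),
#'   `passages`, `feature_id`.
#' @export
build_trajectories <- function(samples_by_passage, features, gold,
                               mask = NULL, metric = c("ld", "reads")) {
  metric <- match.arg(metric)
  passages <- as.integer(names(samples_by_passage))
  if (any(is.na(passages)))
    stop("samples_by_passage must be named by passage number")
  if (length(passages) < 2L) stop("need at least 2 passages")
  o <- order(passages)
  passages <- passages[o]
  samples_by_passage <- samples_by_passage[o]
  if (is.logical(gold)) gold <- features$id[gold]
  vals <- sapply(samples_by_passage, function(s) {
    m <- linear_density(s, features, mask = mask,
                        exclude_repeats = !is.null(mask))
    v <- if (metric == "ld") m$ld else m$total_reads
    names(v) <- m$feature_id
    ne_normalize(v, gold)
  })
  vals <- matrix(vals, nrow = nrow(features),
                 dimnames = list(features$id, passages))
  ok <- rowSums(!is.na(vals)) >= 2L
  if (any(!ok))
    warning(sum(!ok), " features with <2 defined passages skipped")
  structure(list(values = vals[ok, , drop = FALSE], passages = passages,
                 feature_id = features$id[ok]),
            class = "tn_profiles")
}

#' Trapezoidal area under a decay trajectory
#'
#' Integrates trajectory values against passage number by the trapezoidal
#' rule. A constant trajectory of 1 over passages 1..10 sampled at
#' (1,2,3,4,6,8,10) integrates to 9.
#'
#' @param values Numeric trajectory (vector) or a matrix with one trajectory
#'   per row.
#' @param passages Passage grid aligned with the values.
#' @param range Optional `c(lo, hi)` restricting the passage range.
#' @return Numeric AUC (vector if `values` is a matrix).
#' @export
auc_trapz <- function(values, passages, range = NULL) {
  passages <- as.numeric(passages)
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(passages))
    if (!is.null(range)) {
      keep <- passages >= range[1L] & passages <= range[2L]
      if (sum(keep) < 2L) stop("fewer than 2 points in passage range")
      values <- values[, keep, drop = FALSE]
      passages <- passages[keep]
    }
    dx <- diff(passages)
    mid <- (values[, -1L, drop = FALSE] + values[, -ncol(values), drop = FALSE]) / 2
    return(as.numeric(mid %*% dx))
  }
  stopifnot(length(values) == length(passages))
  if (!is.null(range)) {
    keep <- passages >= range[1L] & passages <= range[2L]
    values <- values[keep]; passages <- passages[keep]
  }
  if (length(values) < 2L) stop("fewer than 2 points in passage range")
  sum(diff(passages) * (utils::head(values, -1L) + utils::tail(values, -1L)) / 2)
}

#' Cluster decay trajectories by k-means with distortion-elbow selection
#'
#' Runs k-means over candidate cluster counts and records the distortion
#' (total within-cluster sum of squares). The selected `k` is the candidate
#' with the largest relative distortion drop among candidates whose smallest
#' cluster still holds `min_cluster_size` profiles; high-repeat features
#' (fraction above `max_repeat`) are excluded before clustering because
#' repeat exclusion inflates their apparent densities and distorts cluster
#' shapes. Cluster labels are re-ordered by ascending mean AUC so label 1 is
#' always the most essential-looking cluster.
#'
#' @param profiles A `tn_profiles`.
#' @param k Cluster count, or `"auto"` for elbow selection.
#' @param k_candidates Candidates explored when `k = "auto"`.
#' @param pct_repeated Optional per-profile repeated fraction (same order as
#'   `profiles$feature_id`).
#' @param max_repeat Exclusion threshold on `pct_repeated`.
#' @param min_cluster_size Minimum cluster population for an admissible `k`.
#' @param seed RNG seed.
#' @param nstart Restarts per k-means run.
#' @return List: `clusters` (data.frame feature_id, cluster, auc),
#'   `distortion` (data.frame k, distortion, admissible), `k`, `excluded`.
#' @export
kmeans_decay <- function(profiles, k = "auto", k_candidates = 1:8,
                         pct_repeated = NULL, max_repeat = 0.25,
                         min_cluster_size = 50L, seed = NULL, nstart = 10L) {
  vals <- profiles$values
  ids <- profiles$feature_id
  excluded <- character(0)
  if (!is.null(pct_repeated)) {
    drop <- !is.na(pct_repeated) & pct_repeated > max_repeat
    excluded <- ids[drop]
    vals <- vals[!drop, , drop = FALSE]
    ids <- ids[!drop]
  }
  cc <- stats::complete.cases(vals)
  excluded <- c(excluded, ids[!cc])
  vals <- vals[cc, , drop = FALSE]
  ids <- ids[cc]
  n <- nrow(vals)
  if (n < 2L) stop("fewer profiles than clusters")
  auc <- auc_trapz(vals, profiles$passages)
  with_seed(seed, {
    kc <- k_candidates[k_candidates <= n]
    fits <- list(); distortion <- rep(NA_real_, length(kc))
    minsize <- rep(NA_integer_, length(kc))
    for (i in seq_along(kc)) {
      f <- tryCatch(stats::kmeans(vals, centers = kc[i], nstart = nstart,
                                  iter.max = 100L),
                    error = function(e) NULL)
      if (is.null(f)) next
      fits[[i]] <- f
      distortion[i] <- f$tot.withinss
      minsize[i] <- min(f$size)
    }
    admissible <- !is.na(distortion) & minsize >= min_cluster_size
    if (is.character(k) && k == "auto") {
      if (!any(admissible)) {
        warning("min_cluster_size admits no candidate k; falling back to k=1")
        chosen_i <- 1L
      } else if (sum(admissible) == 1L || distortion[1L] == 0) {
        chosen_i <- which(admissible)[1L]
      } else {
        rel_drop <- c(NA_real_, 1 - distortion[-1L] /
                        distortion[-length(distortion)])
        rel_drop[!admissible] <- -Inf
        rel_drop[1L] <- if (admissible[1L]) 0 else -Inf
        chosen_i <- which.max(rel_drop)
      }
    } else {
      chosen_i <- match(as.integer(k), kc)
      if (is.na(chosen_i)) stop("requested k not among candidates")
      if (!is.null(minsize[chosen_i]) && !is.na(minsize[chosen_i]) &&
          minsize[chosen_i] < min_cluster_size)
        warning("requested k yields a cluster below min_cluster_size")
    }
    fit <- fits[[chosen_i]]
    if (is.null(fit)) stop("k-means failed for the selected k")
    # deterministic labels: ascending mean AUC
    cl <- fit$cluster
    mean_auc <- tapply(auc, cl, mean)
    relabel <- match(cl, as.integer(names(sort(mean_auc))))
    list(clusters = data.frame(feature_id = ids, cluster = relabel,
                               auc = auc, stringsAsFactors = FALSE),
         distortion = data.frame(k = kc, distortion = distortion,
                                 min_cluster = minsize,
                                 admissible = admissible),
         k = kc[chosen_i], excluded = excluded)
  })
}

#' Compare insertion persistence between P and T libraries by AUC
#'
#' For each element, per-replicate AUCs from the promoter (P) and terminator
#' (T) libraries are compared: the fold change is `mean(AUC_P)/mean(AUC_T)`
#' and a one-tailed two-sample t-test is run in the direction of the
#' observed fold change (P < 0.05 significant by default). Exact ties and
#' zero-variance element pairs are reported as not significant.
#'
#' @param auc_p,auc_t Matrices (element x replicate) of AUC values with
#'   matching rownames.
#' @param alpha Significance level.
#' @param paired Use a paired t-test across replicates.
#' @return Data.frame: `element_id`, `auc_p`, `auc_t`, `fold_change`,
#'   `p_value`, `verdict` in {P-enriched, T-enriched, n.s.}.
#' @export
compare_libraries_auc <- function(auc_p, auc_t, alpha = 0.05,
                                  paired = FALSE) {
  stopifnot(is.matrix(auc_p), is.matrix(auc_t),
            nrow(auc_p) == nrow(auc_t))
  ids <- rownames(auc_p)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(auc_p)))
  out <- lapply(seq_len(nrow(auc_p)), function(i) {
    p <- auc_p[i, ]; t_ <- auc_t[i, ]
    mp <- mean(p); mt <- mean(t_)
    fc <- if (mt == 0) ifelse(mp == 0, 1, Inf) else mp / mt
    pv <- NA_real_
    if (stats::sd(c(p, t_)) > 0 && !isTRUE(all.equal(mp, mt))) {
      alt <- if (fc > 1) "greater" else "less"
      pv <- tryCatch(stats::t.test(p, t_, alternative = alt,
                                   paired = paired)$p.value,
                     error = function(e) NA_real_)
    }
    verdict <- if (!is.na(pv) && pv < alpha) {
      if (fc > 1) "P-enriched" else "T-enriched"
    } else "n.s."
    data.frame(element_id = ids[i], auc_p = mp, auc_t = mt,
               fold_change = fc, p_value = pv, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tolerated N/C-terminal extensions and termini-vs-gene AUC ratios
#'
#' Measures, for each gene, how far non-essential (NE) segments from the
#' sliding-window analysis reach into the gene from its 5' (N-terminal) and
#' 3' (C-terminal) ends, in amino acids (bp / 3, floored, strand-aware).
#' When passage samples are supplied, also computes trapezoidal AUCs for
#' each terminus region and the whole gene, and their ratio.
#'
#' @param genes `tn_features` rows for the genes of interest.
#' @param segments Segment table from [segment_genome()].
#' @param samples_by_passage Optional named list (passage to sample) for AUC.
#' @param gold Gold NE ids (required with `samples_by_passage`).
#' @param mask Optional repeat mask.
#' @param auc_range Passage range for the AUC grid.
#' @return Data.frame with `feature_id`, `n_ext_aa`, `c_ext_aa` and, when
#'   samples are given, `auc_gene`, `auc_n`, `auc_c`, `ratio_n`, `ratio_c`.
#' @export
termini_analysis <- function(genes, segments, samples_by_passage = NULL,
                             gold = NULL, mask = NULL, auc_range = NULL) {
  ne <- segments[segments$label == "NE", , drop = FALSE]
  ext_at <- function(pos, gene_start, gene_end) {
    # NE reach from a gene end located at `pos`, clipped to the gene body
    hit <- which(ne$start <= pos & ne$end >= pos)
    if (!length(hit)) return(0L)
    min(ne$end[hit[1L]], gene_end) - max(ne$start[hit[1L]], gene_start) + 1L
  }
  n_bp <- c_bp <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    five <- if (g$strand == "-") g$end else g$start
    three <- if (g$strand == "-") g$start else g$end
    n_bp[i] <- ext_at(five, g$start, g$end)
    c_bp[i] <- ext_at(three, g$start, g$end)
  }
  out <- data.frame(feature_id = genes$id,
                    n_ext_aa = n_bp %/% 3L, c_ext_aa = c_bp %/% 3L,
                    stringsAsFactors = FALSE)
  if (!is.null(samples_by_passage)) {
    if (is.null(gold)) stop("gold NE ids required for AUC computation")
    if (!all(gold %in% genes$id))
      stop("gold NE genes must be included in `genes` for normalization")
    # terminus sub-features: the measured NE reach (at least one codon so
    # the interval is well-formed; zero-extension termini keep AUC ~ 0)
    nb <- pmax(n_bp, 3L); cb <- pmax(c_bp, 3L)
    n_start <- ifelse(genes$strand == "-", genes$end - nb + 1L, genes$start)
    n_end <- ifelse(genes$strand == "-", genes$end, genes$start + nb - 1L)
    c_start <- ifelse(genes$strand == "-", genes$start, genes$end - cb + 1L)
    c_end <- ifelse(genes$strand == "-", genes$start + cb - 1L, genes$end)
    feats <- rbind(
      data.frame(id = genes$id, ftype = "gene", start = genes$start,
                 end = genes$end, stringsAsFactors = FALSE),
      data.frame(id = paste0(genes$id, "_N"), ftype = "terminus",
                 start = pmax(1L, n_start), end = n_end,
                 stringsAsFactors = FALSE),
      data.frame(id = paste0(genes$id, "_C"), ftype = "terminus",
                 start = pmax(1L, c_start), end = c_end,
                 stringsAsFactors = FALSE))
    prof <- build_trajectories(samples_by_passage, tn_features(feats),
                               gold = gold, mask = mask)
    a <- auc_trapz(prof$values, prof$passages, range = auc_range)
    names(a) <- prof$feature_id
    out$auc_gene <- unname(a[genes$id])
    out$auc_n <- unname(a[paste0(genes$id, "_N")])
    out$auc_c <- unname(a[paste0(genes$id, "_C")])
    out$ratio_n <- ifelse(out$auc_gene > 0, out$auc_n / out$auc_gene, NA_real_)
    out$ratio_c <- ifelse(out$auc_gene > 0, out$auc_c / out$auc_gene, NA_real_)
  }
  out
}
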