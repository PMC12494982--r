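#' Simulation configuration for synthetic Tn-seq libraries
#'
#' Bundles every parameter of the synthetic-data generator. Defaults encode
#' the stated world the analysis assumes: four essentiality classes with
#' per-base passage-1 insertion probabilities E = 0.01 (termini-only),
#' F1 = 0.15, F2 = 0.45, NE = 0.92; multiplicative per-passage survival
#' E = 0.05, F1 = 0.3, F2 = 0.7, NE = 0.97; overdispersed read counts with a
#' floor of 2 reads per insertion (single-read insertions are discarded by
#' the standard filter, so the generator never emits them); essential genes
#' insertable only in a `termini_frac` stretch at each end; and a
#' promoter-library (P) retention bonus for insertions upstream of essential
#' genes that the terminator library (T) does not receive.
#'
#' @param genome_length Genome length in bp (>= 1000).
#' @param n_genes Number of genes to tile.
#' @param class_fractions Named proportions over E, F1, F2, NE summing to 1.
#' @param density_p1 Named per-class per-base insertion probability at
#'   passage 1. For E genes the probability applies only within the termini.
#' @param decay_rate Named per-class multiplicative survival per passage.
#' @param read_dispersion Overdispersion of read counts (negative binomial
#'   `size = 1/read_dispersion`); 0 gives Poisson counts.
#' @param read_mu Mean reads per insertion.
#' @param termini_frac Fraction of an E gene length at each end that is
#'   insertable.
#' @param n_repeats Number of duplicated 21-mers planted in the genome.
#' @param p_regulatory_bias Extra per-passage retention probability for
#'   P-library insertions upstream of E genes.
#' @param upstream_window Width (bp) of the upstream-of-E region subject to
#'   the P/T asymmetry.
#' @param gene_len,gene_len_sd,gap_len Mean/SD of gene lengths and mean
#'   intergenic gap (bp).
#' @param gold_ne_n Size of the designated gold non-essential gene set.
#' @param seed RNG seed; all generator output is a pure function of the
#'   config.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 120000L,
                       n_genes = 100L,
                       class_fractions = c(E = 0.25, F1 = 0.25,
                                           F2 = 0.25, NE = 0.25),
                       density_p1 = c(E = 0.01, F1 = 0.15,
                                      F2 = 0.45, NE = 0.92),
                       decay_rate = c(E = 0.05, F1 = 0.3,
                                      F2 = 0.7, NE = 0.97),
                       read_dispersion = 0.5,
                       read_mu = 267.1,
                       termini_frac = 0.02,
                       n_repeats = 5L,
                       p_regulatory_bias = 0.25,
                       upstream_window = 150L,
                       gene_len = 900L, gene_len_sd = 100L, gap_len = 150L,
                       gold_ne_n = 29L,
                       seed = 1L) {
  cls <- c("E", "F1", "F2", "NE")
  stopifnot(genome_length >= 1000L, n_genes >= 1L)
  if (!setequal(names(class_fractions), cls) ||
      abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must be named over E,F1,F2,NE and sum to 1")
  for (v in list(density_p1, decay_rate)) {
    if (!setequal(names(v), cls)) stop("per-class parameters need names E,F1,F2,NE")
    if (any(v < 0 | v > 1)) stop("per-class probabilities must lie in [0,1]")
  }
  stop_if_not_scalar_prob(termini_frac, "termini_frac")
  stop_if_not_scalar_prob(p_regulatory_bias, "p_regulatory_bias")
  if (read_dispersion < 0) stop("read_dispersion must be >= 0")
  if (read_mu < 2) stop("read_mu must be >= 2 (read floor)")
  if (n_repeats > 0 && genome_length < 84L * (n_repeats + 1L))
    stop("genome_length too small to host requested repeats")
  structure(list(genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes),
                 class_fractions = class_fractions[cls],
                 density_p1 = density_p1[cls], decay_rate = decay_rate[cls],
                 read_dispersion = read_dispersion, read_mu = read_mu,
                 termini_frac = termini_frac, n_repeats = as.integer(n_repeats),
                 p_regulatory_bias = p_regulatory_bias,
                 upstream_window = as.integer(upstream_window),
                 gene_len = gene_len, gene_len_sd = gene_len_sd,
                 gap_len = gap_len, gold_ne_n = as.integer(gold_ne_n),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random genome with planted duplicated 21-mers
#'
#' Draws a uniform A/C/G/T sequence and copies `n_repeats` 21-mers from
#' random source positions to random non-overlapping destinations (every
#' second copy reverse-complemented), creating exact repeats the 21-bp
#' repeat-mask scan must find. Planted positions are recorded in the
#' `planted_repeats` attribute as ground truth.
#'
#' @param cfg A `sim_config`.
#' @return A `tn_genome` with attribute `planted_repeats`
#'   (data.frame: src, dst, revcomp).
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    L <- cfg$genome_length
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    planted <- data.frame(src = integer(), dst = integer(), revcomp = logical())
    if (cfg$n_repeats > 0L) {
      k <- 21L
      n_slots <- L %/% 42L
      if (n_slots < 2L * cfg$n_repeats)
        stop("genome_length too small to host requested repeats")
      slots <- (sample(n_slots, 2L * cfg$n_repeats) - 1L) * 42L + 1L
      src <- slots[seq_len(cfg$n_repeats)]
      dst <- slots[cfg$n_repeats + seq_len(cfg$n_repeats)]
      rc <- seq_len(cfg$n_repeats) %% 2L == 0L
      sv <- strsplit(seq, "")[[1L]]
      for (i in seq_len(cfg$n_repeats)) {
        unit <- substr(seq, src[i], src[i] + k - 1L)
        if (rc[i]) unit <- revcomp(unit)
        sv[dst[i]:(dst[i] + k - 1L)] <- strsplit(unit, "")[[1L]]
      }
      seq <- paste(sv, collapse = "")
      planted <- data.frame(src = src, dst = dst, revcomp = rc)
    }
    g <- tn_genome(seq, id = sprintf("sim_genome_seed%d", cfg$seed))
    attr(g, "planted_repeats") <- planted
    g
  })
}

#' Generate a synthetic annotation with known essentiality classes
#'
#' Tiles non-overlapping genes (lengths ~ N(`gene_len`, `gene_len_sd`),
#' rounded to codons) separated by intergenic gaps, groups consecutive genes
#' into operons, assigns each gene a true class by `class_fractions`, places
#' a TSS upstream of each operon start (and a TTS downstream of ~80% of
#' operon ends), flags a gold non-essential subset, and derives
#' UTR5/UTR3/iGiO elements.
#'
#' @param cfg A `sim_config`.
#' @param genome A `tn_genome` from [generate_genome()].
#' @return A `tn_features` table with `true_class` and `gold_ne` columns.
#' @export
generate_annotation <- function(cfg, genome) {
  stopifnot(inherits(cfg, "sim_config"), inherits(genome, "tn_genome"))
  with_seed(cfg$seed + 1L, {
    n <- cfg$n_genes
    len <- pmax(300L, round(stats::rnorm(n, cfg$gene_len, cfg$gene_len_sd)))
    len <- as.integer(len - len %% 3L)
    gap <- pmax(60L, round(stats::rnorm(n, cfg$gap_len, cfg$gap_len / 5)))
    need <- sum(len) + sum(gap) + cfg$gap_len
    if (need > genome$length)
      stop(sprintf("genome_length %d too small for %d genes (need ~%d bp)",
                   genome$length, n, need))
    start <- cfg$gap_len + cumsum(c(0L, (len + gap)[-n])) + 1L
    end <- start + len - 1L
    # largest-remainder apportionment of classes, then a seeded shuffle
    cls <- c("E", "F1", "F2", "NE")
    exact <- cfg$class_fractions * n
    cnt <- floor(exact)
    rem <- n - sum(cnt)
    if (rem > 0) {
      ord <- order(exact - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1L
    }
    true_class <- sample(rep(cls, times = cnt))
    # operons: consecutive runs of 1-4 genes sharing a strand
    op_sizes <- integer(0)
    while (sum(op_sizes) < n)
      op_sizes <- c(op_sizes, sample(1:4, 1L))
    op_sizes[length(op_sizes)] <- op_sizes[length(op_sizes)] -
      (sum(op_sizes) - n)
    op_sizes <- op_sizes[op_sizes > 0L]
    operon_id <- rep(sprintf("op%03d", seq_along(op_sizes)), times = op_sizes)
    strand <- rep(sample(c("+", "-"), length(op_sizes), replace = TRUE),
                  times = op_sizes)
    gold <- logical(n)
    ne_idx <- which(true_class == "NE")
    if (length(ne_idx))
      gold[sample(ne_idx, min(cfg$gold_ne_n, length(ne_idx)))] <- TRUE
    genes <- data.frame(id = sprintf("g%04d", seq_len(n)), ftype = "gene",
                        start = start, end = end, strand = strand,
                        operon_id = operon_id,
                        cog = sample(c("J", "K", "L", "D", "T", "G", "E", "S"),
                                     n, replace = TRUE),
                        gold_ne = gold, true_class = true_class,
                        stringsAsFactors = FALSE)
    # TSS upstream of each operon start, TTS downstream of most operon ends
    pts <- list()
    for (oi in unique(operon_id)) {
      og <- genes[genes$operon_id == oi, ]
      st <- og$strand[1L]
      first <- if (st == "+") og[which.min(og$start), ] else og[which.max(og$end), ]
      last <- if (st == "+") og[which.max(og$end), ] else og[which.min(og$start), ]
      off <- sample(20:60, 1L)
      tss <- if (st == "+") first$start - off else first$end + off
      if (tss >= 1L && tss <= genome$length)
        pts[[length(pts) + 1L]] <- data.frame(
          id = paste0("tss_", oi), ftype = "TSS", start = tss, end = tss,
          strand = st, operon_id = oi, cog = NA_character_, gold_ne = FALSE,
          true_class = NA_character_, stringsAsFactors = FALSE)
      if (stats::runif(1) < 0.8) {
        off <- sample(10:60, 1L)
        tts <- if (st == "+") last$end + off else last$start - off
        if (tts >= 1L && tts <= genome$length)
          pts[[length(pts) + 1L]] <- data.frame(
            id = paste0("tts_", oi), ftype = "TTS", start = tts, end = tts,
            strand = st, operon_id = oi, cog = NA_character_, gold_ne = FALSE,
            true_class = NA_character_, stringsAsFactors = FALSE)
      }
    }
    feats <- tn_features(rbind(genes, do.call(rbind, pts)), genome$length)
    derive_regulatory_elements(feats, genome$length)
  })
}

# per-base class map: 0 non-insertable, 1 E-termini, 2 F1, 3 F2, 4 NE gene,
# 5 intergenic (NE-like), 6 upstream-of-E (library-asymmetric)
position_class_map <- function(cfg, genome, annot) {
  L <- genome$length
  cm <- rep(5L, L)
  genes <- annot[annot$ftype == "gene", , drop = FALSE]
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    idx <- g$start:g$end
    cm[idx] <- switch(g$true_class, E = 0L, F1 = 2L, F2 = 3L, NE = 4L)
    if (g$true_class == "E") {
      t_len <- max(1L, round(cfg$termini_frac * (g$end - g$start + 1L)))
      cm[g$start:(g$start + t_len - 1L)] <- 1L
      cm[(g$end - t_len + 1L):g$end] <- 1L
    }
  }
  # upstream-of-E windows, strand-aware, only over intergenic territory
  egenes <- genes[genes$true_class == "E", , drop = FALSE]
  for (i in seq_len(nrow(egenes))) {
    g <- egenes[i, ]
    win <- if (g$strand == "-") {
      (g$end + 1L):min(L, g$end + cfg$upstream_window)
    } else {
      max(1L, g$start - cfg$upstream_window):(g$start - 1L)
    }
    win <- win[win >= 1L & win <= L]
    cm[win][cm[win] == 5L] <- 6L
  }
  cm
}

draw_reads <- function(n, cfg) {
  mu <- cfg$read_mu - 2
  extra <- if (cfg$read_dispersion <= 0) stats::rpois(n, mu)
           else stats::rnbinom(n, mu = mu, size = 1 / cfg$read_dispersion)
  as.integer(2L + extra)
}

#' Simulate serial-passage insertion samples for one library
#'
#' Draws a shared passage-1 master pool of insertion positions (per-base
#' Bernoulli at the class density) and thins it independently per passage and
#' replicate with the class survival probability
#' `decay_rate^(passage - 1)`. Intergenic positions behave like NE sequence.
#' Positions upstream of essential genes decay with the quasi-non-essential
#' rate in both libraries (perturbing essential-gene regulation is costly),
#' but the P library adds `p_regulatory_bias` to the retention probability
#' there, emulating the promoter-library asymmetry in regulatory regions.
#' Read counts per retained insertion are overdispersed with a floor of 2.
#'
#' @param cfg A `sim_config`.
#' @param genome A `tn_genome`.
#' @param annot Annotation from [generate_annotation()].
#' @param library `"P"` or `"T"`.
#' @param passages Integer passages in 1..10.
#' @param replicates Number of replicates per passage.
#' @return A list of `tn_sample` objects, one per passage x replicate.
#' @export
simulate_library <- function(cfg, genome, annot, library = c("P", "T"),
                             passages = c(1L, 2L, 3L, 4L, 6L, 8L, 10L),
                             replicates = 2L) {
  library <- match.arg(library)
  if (length(passages) == 0L) stop("empty passage list")
  if (!all(passages %in% 1:10)) stop("passages must lie in 1..10")
  cm <- position_class_map(cfg, genome, annot)
  dens <- c(0, cfg$density_p1["E"], cfg$density_p1["F1"], cfg$density_p1["F2"],
            cfg$density_p1["NE"], cfg$density_p1["NE"], cfg$density_p1["NE"])
  base_decay <- c(1, cfg$decay_rate["E"], cfg$decay_rate["F1"],
                  cfg$decay_rate["F2"], cfg$decay_rate["NE"],
                  cfg$decay_rate["NE"], cfg$decay_rate["F2"])
  with_seed(cfg$seed + 101L * (1L + (library == "T")), {
    master <- which(stats::runif(genome$length) < dens[cm + 1L])
    mclass <- cm[master]
    out <- list()
    for (p in sort(as.integer(passages))) {
      surv <- base_decay[mclass + 1L]^(p - 1L)
      if (library == "P")
        surv[mclass == 6L] <- pmin(1, surv[mclass == 6L] + cfg$p_regulatory_bias)
      for (r in seq_len(replicates)) {
        keep <- stats::runif(length(master)) < surv
        pos <- master[keep]
        out[[sprintf("%s_p%d_r%d", library, p, r)]] <-
          tn_sample(pos, draw_reads(length(pos), cfg),
                    library = library, passage = p, replicate = r)
      }
    }
    out
  })
}

#' Emit IR-tagged FASTQ reads for an insertion sample
#'
#' Each insertion with `n` reads yields `n` identical records: the
#' inverted-repeat tag followed by the genomic sequence starting at the
#' insertion position. The chromosome is treated as circular by default, so
#' anchors near the sequence end wrap through the origin (`end_policy =
#' "truncate"` clips them instead). Qualities are uniform.
#'
#' @param sample A `tn_sample`.
#' @param genome A `tn_genome`.
#' @param ir_tag IR tag sequence prepended to each read.
#' @param read_length Total read length (> nchar(ir_tag) + 20).
#' @param end_policy `"wrap"` (circular genome) or `"truncate"`.
#' @param path Optional FASTQ output path.
#' @return Invisibly, a `DNAStringSet` of reads (named by insertion).
#' @export
emit_reads <- function(sample, genome, ir_tag = "TACGGACTTTATC",
                       read_length = 50L, end_policy = c("wrap", "truncate"),
                       path = NULL) {
  end_policy <- match.arg(end_policy)
  anchor_len <- read_length - nchar(ir_tag)
  if (anchor_len <= 20L)
    stop("read_length must exceed nchar(ir_tag) + 20")
  pos <- rep(sample$positions, times = sample$reads)
  if (length(pos) == 0L) {
    reads <- Biostrings::DNAStringSet()
  } else {
    seqx <- if (end_policy == "wrap")
      paste0(genome$sequence, substr(genome$sequence, 1L, anchor_len - 1L))
    else genome$sequence
    anchors <- substring(seqx, pos, pos + anchor_len - 1L)
    reads <- Biostrings::DNAStringSet(paste0(ir_tag, anchors))
    names(reads) <- sprintf("ins%d_%d", pos, stats::ave(pos, pos, FUN = seq_along))
  }
  if (!is.null(path)) {
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = quals)
  }
  invisible(reads)
}
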