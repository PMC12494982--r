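# shared fixtures and independent oracles, all built in code at test time

random_genome <- function(length, seed) {
  set.seed(seed)
  tn_genome(paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = ""))
}

# brute-force repeat oracle: counts occurrences of every k-mer with
# fixed-string search over the genome and its reverse complement
brute_repeat_mask <- function(seq, k = 21L) {
  L <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  flags <- logical(L)
  for (i in seq_len(L - k + 1L)) {
    s <- substr(seq, i, i + k - 1L)
    n_f <- length(gregexpr(s, seq, fixed = TRUE)[[1L]])
    if (gregexpr(s, seq, fixed = TRUE)[[1L]][1L] == -1L) n_f <- 0L
    hit_r <- gregexpr(s, rc, fixed = TRUE)[[1L]]
    n_r <- if (hit_r[1L] == -1L) 0L else length(hit_r)
    if (n_f + n_r >= 2L) flags[i:(i + k - 1L)] <- TRUE
  }
  flags
}

# standard small simulation used across module tests
small_sim <- function(seed = 1L, n_genes = 60L, genome_length = 80000L,
                      passages = 1L, replicates = 2L, ...) {
  cfg <- sim_config(genome_length = genome_length, n_genes = n_genes,
                    seed = seed, ...)
  g <- generate_genome(cfg)
  an <- generate_annotation(cfg, g)
  sp <- simulate_library(cfg, g, an, "P", passages, replicates)
  st <- simulate_library(cfg, g, an, "T", passages, replicates)
  list(cfg = cfg, genome = g, annot = an,
       genes = an[an$ftype == "gene", , drop = FALSE],
       mask = compute_repeat_mask(g), P = sp, T = st)
}

merged_pt <- function(sim, passage = 1L, trim = 0.05) {
  nm <- sprintf("_p%d_", passage)
  merge_samples(c(sim$P[grepl(nm, names(sim$P), fixed = TRUE)],
                  sim$T[grepl(nm, names(sim$T), fixed = TRUE)]), trim = trim)
}

samples_by_passage <- function(sim, passages, trim = 0.05) {
  out <- lapply(passages, function(p) merged_pt(sim, p, trim))
  names(out) <- passages
  out
}

# best label-to-class agreement over all cluster-label permutations
best_label_agreement <- function(clusters, truth) {
  labs <- sort(unique(clusters))
  classes <- sort(unique(truth))
  stopifnot(length(labs) <= 6L)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(classes[seq_along(labs)])) {
    mapped <- p[match(clusters, labs)]
    best <- max(best, mean(mapped == truth))
  }
  best
}

# closed-form upper-tail hypergeometric by direct combinatorial summation
hyper_upper_enum <- function(x, K, N, n) {
  i <- x:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
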