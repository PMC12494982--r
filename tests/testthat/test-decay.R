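test_that("trapezoidal AUC matches closed forms exactly", {
  grid <- c(1, 2, 3, 4, 6, 8, 10)
  expect_equal(auc_trapz(rep(1, 7), grid), 9, tolerance = 1e-12)
  expect_equal(auc_trapz(c(1, 0), c(1, 2)), 0.5, tolerance = 1e-12)
  # linear decay y = (10 - x) / 9 over the gene grid: analytic area 4.5
  y <- (10 - grid) / 9
  expect_equal(auc_trapz(y, grid), 4.5, tolerance = 1e-12)
  # linearity and flat-trajectory identities
  expect_equal(auc_trapz(3.7 * y, grid), 3.7 * auc_trapz(y, grid),
               tolerance = 1e-12)
  expect_equal(auc_trapz(rep(2.5, 4), c(1, 2, 4, 8)), 2.5 * 7,
               tolerance = 1e-12)
  # matrix form agrees with vector form and range restriction works
  m <- rbind(a = y, b = rep(1, 7))
  expect_equal(auc_trapz(m, grid), c(4.5, 9), tolerance = 1e-12)
  expect_equal(auc_trapz(m, grid, range = c(1, 8))[2L], 7, tolerance = 1e-12)
  expect_error(auc_trapz(1, 1), "2 points")
})

test_that("trajectories are NE-normalized per passage", {
  sim <- small_sim(seed = 111, n_genes = 60L,
                   passages = c(1L, 2L, 4L, 6L, 8L))
  gold <- sim$genes$id[sim$genes$gold_ne]
  byp <- samples_by_passage(sim, c(1L, 2L, 4L, 6L, 8L))
  prof <- build_trajectories(byp, sim$genes, gold = gold, mask = sim$mask)
  expect_equal(ncol(prof$values), 5L)
  tc <- sim$genes$true_class[match(prof$feature_id, sim$genes$id)]
  gold_traj <- colMeans(prof$values[prof$feature_id %in% gold, ,
                                    drop = FALSE])
  expect_true(all(abs(gold_traj - 1) < 0.05))
  e_traj <- prof$values[tc == "E", , drop = FALSE]
  expect_true(all(e_traj < 0.05))
  # AUC orders classes by decay severity
  auc <- auc_trapz(prof$values, prof$passages)
  mu <- tapply(auc, tc, mean)
  expect_true(mu["E"] < mu["F1"] && mu["F1"] < mu["F2"] &&
                mu["F2"] < mu["NE"])
})

test_that("k-means elbow handles degenerate and constrained cases", {
  flat <- structure(list(values = matrix(1, 60, 3,
                                         dimnames = list(NULL, 1:3)),
                         passages = 1:3,
                         feature_id = as.character(1:60)),
                    class = "tn_profiles")
  km <- kmeans_decay(flat, seed = 1, min_cluster_size = 5L)
  expect_equal(km$k, 1L)
  expect_equal(km$distortion$distortion[1L], 0)

  # min_cluster_size larger than n/k forces a smaller k
  set.seed(2)
  vals <- rbind(matrix(rnorm(40 * 3, 0, 0.01), 40),
                matrix(rnorm(40 * 3, 1, 0.01), 40))
  colnames(vals) <- 1:3
  prof <- structure(list(values = vals, passages = 1:3,
                         feature_id = as.character(1:80)),
                    class = "tn_profiles")
  km2 <- kmeans_decay(prof, seed = 3, min_cluster_size = 30L,
                      k_candidates = 1:6)
  expect_lte(km2$k, 2L)

  # same seed, same labels
  km3 <- kmeans_decay(prof, seed = 9, min_cluster_size = 10L)
  km4 <- kmeans_decay(prof, seed = 9, min_cluster_size = 10L)
  expect_identical(km3$clusters, km4$clusters)
})

test_that("high-repeat profiles are excluded before clustering", {
  set.seed(4)
  vals <- matrix(rnorm(60 * 3, 0.5, 0.05), 60)
  colnames(vals) <- 1:3
  prof <- structure(list(values = vals, passages = 1:3,
                         feature_id = sprintf("f%02d", 1:60)),
                    class = "tn_profiles")
  pr <- rep(0, 60); pr[1:5] <- 0.5
  km <- kmeans_decay(prof, k = 1L, pct_repeated = pr,
                     min_cluster_size = 5L, seed = 1)
  expect_equal(sort(km$excluded), sprintf("f%02d", 1:5))
  expect_equal(nrow(km$clusters), 55L)
})

test_that("library AUC comparison is symmetric and calibrated", {
  set.seed(5)
  a <- matrix(rnorm(20, 5, 0.2), 10, 2,
              dimnames = list(letters[1:10], NULL))
  cmp_same <- compare_libraries_auc(a, a)
  expect_true(all(cmp_same$fold_change == 1))
  expect_true(all(cmp_same$verdict == "n.s."))

  b <- a * 2
  fwd <- compare_libraries_auc(a, b)
  rev <- compare_libraries_auc(b, a)
  expect_equal(fwd$fold_change, 1 / rev$fold_change, tolerance = 1e-12)
})

test_that("P-library bias concentrates P-enriched verdicts upstream of E genes", {
  sim <- small_sim(seed = 8, n_genes = 100L, genome_length = 130000L,
                   passages = c(1L, 2L, 4L, 6L, 8L))
  genes <- sim$genes
  gold <- genes$id[genes$gold_ne]
  eg <- genes[genes$true_class == "E", ]
  up <- data.frame(id = paste0("up_", eg$id), ftype = "promoter",
                   start = ifelse(eg$strand == "-", eg$end + 1L,
                                  pmax(1L, eg$start - 150L)),
                   end = ifelse(eg$strand == "-",
                                pmin(sim$genome$length, eg$end + 150L),
                                eg$start - 1L),
                   strand = eg$strand)
  elems <- tn_features(rbind(up, genes[, c("id", "ftype", "start", "end",
                                           "strand")]))
  passages <- c(1L, 2L, 4L, 6L, 8L)
  rep_auc <- function(samps, lib, rep) {
    byp <- lapply(stats::setNames(as.character(passages), passages),
                  function(p) samps[[sprintf("%s_p%s_r%d", lib, p, rep)]])
    pr <- build_trajectories(byp, elems, gold = gold, mask = sim$mask)
    a <- auc_trapz(pr$values, pr$passages)
    stats::setNames(a, pr$feature_id)
  }
  ap <- cbind(rep_auc(sim$P, "P", 1L), rep_auc(sim$P, "P", 2L))
  at <- cbind(rep_auc(sim$T, "T", 1L), rep_auc(sim$T, "T", 2L))
  cmp_up <- compare_libraries_auc(ap[up$id, , drop = FALSE],
                                  at[up$id, , drop = FALSE])
  expect_gte(mean(cmp_up$verdict == "P-enriched"), 0.6)
  expect_gt(stats::median(cmp_up$fold_change), 1.2)
  # NE gene bodies see no systematic asymmetry
  ne_ids <- genes$id[genes$true_class == "NE"]
  cmp_ne <- compare_libraries_auc(ap[ne_ids, , drop = FALSE],
                                  at[ne_ids, , drop = FALSE])
  expect_equal(stats::median(cmp_ne$fold_change), 1, tolerance = 0.05)
  expect_lt(mean(cmp_ne$verdict == "P-enriched"), 0.4)
})

test_that("termini extensions are read off NE segments in amino acids", {
  segs <- data.frame(start = c(1L, 1001L, 1016L, 2001L),
                     end = c(1000L, 1015L, 2000L, 3000L),
                     label = c("NE", "NE", "E", "NE"),
                     length = c(1000L, 15L, 985L, 1000L),
                     pct_repeated = 0)
  gene <- data.frame(id = "g", ftype = "gene", start = 1001L, end = 2000L,
                     strand = "+")
  ta <- termini_analysis(gene, segs)
  expect_equal(ta$n_ext_aa, 5L)   # 15 bp NE head
  expect_equal(ta$c_ext_aa, 0L)
  # minus strand swaps the termini
  gene_m <- transform(gene, strand = "-")
  tam <- termini_analysis(gene_m, segs)
  expect_equal(tam$n_ext_aa, 0L)
  expect_equal(tam$c_ext_aa, 5L)
  # fully NE gene: both extensions cap at the gene span
  segs2 <- data.frame(start = 1L, end = 3000L, label = "NE", length = 3000L,
                      pct_repeated = 0)
  ta2 <- termini_analysis(gene, segs2)
  expect_equal(ta2$n_ext_aa, 1000L %/% 3L)
  expect_equal(ta2$c_ext_aa, 1000L %/% 3L)
})

test_that("simulated tolerant termini yield ~10 aa extensions", {
  # E genes of 1500 bp with 2% termini inserted at NE-like density: the
  # detectable NE reach at each end is ~30 bp = 10 aa, up to window blur
  cfg <- sim_config(genome_length = 80000L, n_genes = 40L,
                    class_fractions = c(E = 0.5, F1 = 0, F2 = 0, NE = 0.5),
                    density_p1 = c(E = 0.9, F1 = 0.15, F2 = 0.45, NE = 0.92),
                    gene_len = 1500L, gene_len_sd = 0L, termini_frac = 0.02,
                    n_repeats = 0L, seed = 21L)
  g <- generate_genome(cfg)
  an <- generate_annotation(cfg, g)
  genes <- an[an$ftype == "gene", ]
  s <- merge_samples(c(simulate_library(cfg, g, an, "P", 1L, 2L),
                       simulate_library(cfg, g, an, "T", 1L, 2L)), trim = 0)
  seg <- segment_genome(s, g, seed = 2)
  ta <- termini_analysis(genes[genes$true_class == "E", ], seg)
  expect_equal(mean(ta$n_ext_aa), 10, tolerance = 0.5)
  expect_equal(mean(ta$c_ext_aa), 10, tolerance = 0.5)
})

test_that("AUC ratios compare termini with whole genes", {
  sim <- small_sim(seed = 117, n_genes = 60L,
                   passages = c(1L, 2L, 4L, 6L, 8L))
  gold <- sim$genes$id[sim$genes$gold_ne]
  byp <- samples_by_passage(sim, c(1L, 2L, 4L, 6L, 8L))
  merged1 <- byp[["1"]]
  seg <- segment_genome(merged1, sim$genome, mask = sim$mask, seed = 3)
  genes <- rbind(sim$genes[sim$genes$true_class == "E", ],
                 sim$genes[sim$genes$gold_ne, ])
  ta <- termini_analysis(genes, seg, samples_by_passage = byp,
                         gold = gold, mask = sim$mask)
  expect_true(all(c("auc_gene", "ratio_n", "ratio_c") %in% names(ta)))
  gold_rows <- ta[ta$feature_id %in% gold, ]
  # NE genes: termini decay like the gene itself, ratio near 1
  expect_equal(stats::median(gold_rows$ratio_n, na.rm = TRUE), 1,
               tolerance = 0.25)
})
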