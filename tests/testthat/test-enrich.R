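mk_s <- function(pos, reads = rep(5L, length(pos))) tn_sample(pos, reads)

test_that("valid positions are the four-way intersection", {
  a <- mk_s(c(1L, 5L, 9L, 20L))
  expect_equal(valid_positions(a, a, a, a), a$positions)
  expect_warning(
    vp <- valid_positions(a, mk_s(integer()), a, a), "empty")
  expect_length(vp, 0L)
  expect_length(valid_positions(mk_s(1:5), mk_s(6:10), mk_s(1:5),
                                mk_s(1:5)), 0L)
  # brute-force set oracle on a constructed fixture
  set.seed(120)
  sets <- replicate(4, sort(sample(1:60, 30)), simplify = FALSE)
  oracle <- sort(Filter(function(p)
    all(vapply(sets, function(s) p %in% s, TRUE)), 1:60))
  got <- valid_positions(mk_s(sets[[1]]), mk_s(sets[[2]]),
                         mk_s(sets[[3]]), mk_s(sets[[4]]))
  expect_equal(got, oracle)
})

test_that("TMM factors satisfy their defining identities", {
  set.seed(121)
  ref <- rnbinom(300, mu = 150, size = 2) + 1L
  expect_equal(unname(tmm_factors(cbind(a = ref, b = ref))[2L]), 1)
  f2 <- tmm_factors(cbind(a = ref, b = 2L * ref))
  expect_equal(unname(f2[2L]), 2)
  # scale equivariance: normalized counts return to parity
  other <- rnbinom(300, mu = 150, size = 2) + 1L
  f <- tmm_factors(cbind(a = ref, b = other))
  fc <- tmm_factors(cbind(a = ref, b = 5L * other))
  expect_equal(unname(fc[2L] / f[2L]), 5, tolerance = 1e-9)
  # single shared position degenerates to its ratio
  m1 <- matrix(c(10L, 30L), 1, 2, dimnames = list("7", c("a", "b")))
  expect_equal(unname(tmm_factors(m1)[2L]), 3)
  expect_error(tmm_factors(matrix(c(1, 0, 0, 1), 2, 2)), "co-detected")
})

test_that("TMM matches the edgeR reference implementation", {
  suppressMessages(library(edgeR))
  set.seed(122)
  m <- matrix(rnbinom(400 * 4, mu = 200, size = 2) + 1L, ncol = 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  mine <- tmm_factors(m, ref = 1L) / (colSums(m) / colSums(m)[1L])
  edge <- edgeR::calcNormFactors(m, method = "TMM", refColumn = 1L,
                                 doWeighting = FALSE)
  expect_equal(unname(mine), unname(edge / edge[1L]), tolerance = 0.01)
})

test_that("position enrichment flags amplified positions, not neutral ones", {
  n <- 50L
  set.seed(123)
  base <- rnbinom(n, mu = 200, size = 50) + 100
  reps <- function(k) sapply(seq_len(k), function(i)
    base * runif(n, 0.98, 1.02))
  p1 <- reps(4L)
  p10 <- reps(4L)
  # one position amplified 10x with tight replicates
  p10[7L, ] <- p1[7L, ] * c(10, 10.2, 9.9, 10.1)
  rownames(p1) <- rownames(p10) <- 1:n
  enr <- position_enrichment(p1, p10)
  expect_true(enr$enriched[7L])
  expect_lte(mean(enr$enriched[-7L]), 0.05)
  expect_true(all(enr$p_adj >= enr$p_raw, na.rm = TRUE))
  expect_true(all(enr$p_adj <= 1, na.rm = TRUE))

  # equal counts: log2fc 0, not enriched; Bonferroni with m = 1 is identity
  eq <- matrix(c(5, 5), 1, 2, dimnames = list("1", NULL))
  e1 <- position_enrichment(eq, eq)
  expect_equal(e1$log2fc, 0)
  expect_false(e1$enriched)
  one <- position_enrichment(matrix(c(3, 4), 1), matrix(c(9, 16), 1))
  expect_equal(one$p_adj, one$p_raw)

  # zero passage-1 mean: flagged, not tested
  z <- position_enrichment(matrix(c(0, 0), 1), matrix(c(5, 6), 1))
  expect_false(z$tested)
  expect_true(is.na(z$p_raw))
})

test_that("positions map to annotation categories", {
  feats <- tn_features(rbind(
    data.frame(id = "ge", ftype = "gene", start = 1000L, end = 2000L,
               strand = "+"),
    data.frame(id = "gn", ftype = "gene", start = 3000L, end = 4000L,
               strand = "+"),
    data.frame(id = "gm", ftype = "gene", start = 4500L, end = 5000L,
               strand = "-"),
    data.frame(id = "u5", ftype = "UTR5", start = 950L, end = 999L,
               strand = "+"),
    data.frame(id = "ig", ftype = "iGiO", start = 2500L, end = 2600L,
               strand = "+"),
    data.frame(id = "nx", ftype = "noexp", start = 8000L, end = 8500L,
               strand = ".")))
  calls <- data.frame(feature_id = c("ge", "gn", "gm"),
                      category = c("E", "NE", "F2"))
  got <- categorize_positions(c(3500L, 900L, 975L, 2550L, 8200L, 7000L,
                                4200L),
                              feats, calls)
  expect_equal(got$categories[1L], "overlap F2/NE gene")
  expect_true(grepl("upstream E/F1 gene", got$categories[2L]))
  expect_true(grepl("overlap UTR5", got$categories[3L]))
  expect_true(grepl("overlap iGiO", got$categories[4L]))
  expect_equal(got$categories[5L], "overlap non-transcribed")
  expect_equal(got$categories[6L], "not classified")
  # between the 3' ends of two convergent genes (gn +, gm -)
  expect_true(grepl("between two gene ends", got$categories[7L]))
})

test_that("whole-gene enrichment survives top-3 subtraction only when broad", {
  gene <- data.frame(id = "g", start = 1L, end = 1000L)
  pos <- as.character(seq(10L, 990L, by = 20L))  # 50 insertions
  r1 <- stats::setNames(rep(100, 50), pos)
  # uniform 5x amplification: enriched even after removing the top 3
  set.seed(124)
  r10 <- r1 * 5 * runif(50, 0.95, 1.05)
  res <- whole_gene_enrichment(gene, r1, r10)
  expect_equal(res$verdict, "enriched")
  expect_equal(res$n_insertions_tested, 47L)
  # enrichment driven by exactly 3 hot insertions disappears
  r10b <- r1 * runif(50, 0.97, 1.03)
  r10b[1:3] <- r1[1:3] * 50
  expect_equal(whole_gene_enrichment(gene, r1, r10b)$verdict,
               "not enriched")
  # no change at all
  expect_equal(whole_gene_enrichment(gene, r1, r1)$verdict, "not enriched")
  # too few insertions is not evaluable
  few <- stats::setNames(rep(10, 4), as.character(c(10L, 20L, 30L, 40L)))
  expect_equal(whole_gene_enrichment(gene, few, few)$verdict,
               "not evaluable")
})

test_that("COG hypergeometric matches exhaustive enumeration (N <= 25)", {
  for (N in c(8L, 15L, 25L)) {
    set.seed(N)
    bg <- data.frame(id = sprintf("g%02d", 1:N),
                     cog = sample(c("J", "K", "L"), N, replace = TRUE))
    for (n_hit in c(1L, 3L, min(6L, N))) {
      hits <- sample(bg$id, n_hit)
      res <- cog_enrichment(hits, bg)
      for (i in seq_len(nrow(res))) {
        expect_equal(res$p_hyper[i],
                     hyper_upper_enum(res$n_hit[i], res$n_category[i],
                                      N, n_hit),
                     tolerance = 1e-12)
      }
      expect_true(all(res$q_bh >= res$p_hyper - 1e-12))
      expect_true(all(res$q_bh <= 1))
    }
  }
  # hits covering one whole category make it the most significant
  bg <- data.frame(id = sprintf("g%02d", 1:20),
                   cog = rep(c("J", "K", "L", "D"), each = 5))
  res <- cog_enrichment(bg$id[bg$cog == "K"], bg)
  expect_equal(res$cog[which.min(res$p_hyper)], "K")
  # one-category universe: p = 1
  bg1 <- data.frame(id = c("a", "b", "c"), cog = "S")
  expect_equal(cog_enrichment(c("a"), bg1)$p_hyper, 1)
  expect_error(cog_enrichment("zz", bg), "subset")
})

test_that("uniform null hits rarely reach COG significance", {
  set.seed(125)
  bg <- data.frame(id = sprintf("g%03d", 1:200),
                   cog = sample(c("J", "K", "L", "D", "T", "G"), 200,
                                replace = TRUE))
  calm <- 0L
  for (r in 1:200) {
    hits <- sample(bg$id, 12L)
    if (all(cog_enrichment(hits, bg)$q_bh >= 0.05)) calm <- calm + 1L
  }
  expect_gte(calm, 190L)
})

test_that("binding sites depleted versus flanks reach significance", {
  set.seed(126)
  L <- 20000L
  site_starts <- seq(1000L, 11000L, by = 1000L)[1:11]
  sites <- data.frame(id = paste0("s", 1:11), start = site_starts,
                      end = site_starts + 49L)
  keep <- runif(L) < 0.9
  for (i in 1:11) {
    idx <- sites$start[i]:sites$end[i]
    keep[idx] <- keep[idx] & runif(50) < 0.1   # 90% depletion inside sites
  }
  s <- tn_sample(which(keep), rep(4L, sum(keep)))
  res <- accessibility_test(sites, s, L)
  expect_lt(res$p_ld, 0.05)
  expect_true(all(res$per_site$ld_site < res$per_site$ld_flanks))

  # no depletion: not significant
  pos <- which(runif(L) < 0.5)
  s2 <- tn_sample(pos, rep(4L, length(pos)))
  res2 <- accessibility_test(sites, s2, L)
  expect_gt(res2$p_ld, 0.05)

  # single site: paired test undefined
  res1 <- accessibility_test(sites[1L, ], s, L)
  expect_true(is.na(res1$p_ld))
  expect_equal(nrow(res1$per_site), 1L)
})
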