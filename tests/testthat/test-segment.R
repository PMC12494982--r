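test_that("window track computes densities on non-repeated bases", {
  s <- tn_sample(c(5L, 10L, 40L), c(3L, 3L, 3L))
  tr <- window_ld_track(s, 100L, w = 10L)
  expect_length(tr$ld, 91L)
  expect_equal(tr$ld[1L], 0.2)   # positions 5 and 10 inside [1,10]
  expect_equal(tr$ld[50L], 0)
  flags <- logical(100); flags[1:9] <- TRUE
  mask <- structure(list(flags = flags, k = 21L, mark = "cover"),
                    class = "tn_repeat_mask")
  tr2 <- window_ld_track(s, 100L, mask = mask, w = 10L)
  expect_equal(tr2$ld[1L], 1)    # only base 10 informative, and inserted
  expect_error(window_ld_track(s, 5L, w = 10L), "shorter")
})

test_that("segmentation tiles the genome and recovers planted E gaps", {
  # saturated genome: one NE segment
  sat <- tn_sample(1:2000, rep(5L, 2000))
  seg_sat <- segment_genome(sat, 2000L, seed = 1)
  expect_equal(nrow(seg_sat), 1L)
  expect_equal(seg_sat$label, "NE")
  expect_equal(seg_sat$length, 2000L)

  # empty genome: one E segment
  seg_e <- segment_genome(tn_sample(integer(), integer()), 2000L, seed = 1)
  expect_equal(nrow(seg_e), 1L)
  expect_equal(seg_e$label, "E")

  # planted 300 bp insertion-free gap inside NE background
  set.seed(7)
  pos <- setdiff(which(runif(6000) < 0.9), 3000:3299)
  seg <- segment_genome(tn_sample(pos, rep(4L, length(pos))), 6000L,
                        seed = 7)
  expect_equal(sum(seg$length), 6000L)
  e <- seg[seg$label == "E" & seg$length > 100L, ]
  expect_equal(nrow(e), 1L)
  expect_lte(abs(e$start - 3000L), 31L)
  expect_lte(abs(e$end - 3299L), 31L)
})

test_that("gap boundaries are recovered within one window in 100 replicates", {
  hits <- 0L
  for (r in 1:100) {
    set.seed(1000 + r)
    pos <- setdiff(which(runif(5000) < 0.9), 2400:2699)
    seg <- segment_genome(tn_sample(pos, rep(4L, length(pos))), 5000L,
                          seed = r)
    e <- seg[seg$label == "E" & seg$length > 100L, ]
    if (nrow(e) == 1L && abs(e$start - 2400L) <= 31L &&
        abs(e$end - 2699L) <= 31L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("adding insertions never grows E territory", {
  # structured genome: two insertion-free gaps in an inserted background;
  # the superset densifies the background but never touches the gaps
  set.seed(8)
  gaps <- c(1200:1499, 3000:3399)
  base_pos <- setdiff(which(runif(4000) < 0.5), gaps)
  extra <- setdiff(setdiff(which(runif(4000) < 0.7), gaps), base_pos)
  a <- tn_sample(base_pos, rep(4L, length(base_pos)))
  b <- tn_sample(sort(c(base_pos, extra)),
                 rep(4L, length(base_pos) + length(extra)))
  e_bp <- function(seg) sum(seg$length[seg$label == "E"])
  seg_a <- segment_genome(a, 4000L, seed = 2)
  # fixed classifier: exact monotonicity
  seg_b_fixed <- segment_genome(b, 4000L, cutoff = attr(seg_a, "cutoff"))
  expect_lte(e_bp(seg_b_fixed), e_bp(seg_a))
  # refit classifier: E territory still essentially the planted gaps
  seg_b <- segment_genome(b, 4000L, seed = 2)
  expect_lte(e_bp(seg_b), e_bp(seg_a) + 62L)  # within one window per gap
})

test_that("reported E segments respect length and repeat filters", {
  segs <- data.frame(start = c(1L, 101L, 105L, 205L, 305L),
                     end = c(100L, 104L, 204L, 304L, 404L),
                     label = c("NE", "E", "E", "E", "NE"),
                     length = c(100L, 4L, 100L, 100L, 100L),
                     pct_repeated = c(0, 0, 0.15, 0.05, 0.5))
  kept <- filter_segments(segs)
  expect_equal(kept$start, c(1L, 205L, 305L))  # 4 bp and 15%-repeat E dropped
})

test_that("segment-to-annotation mapping reports per-gene essential fractions", {
  segs <- data.frame(start = c(1L, 501L), end = c(500L, 1000L),
                     label = c("E", "NE"), length = c(500L, 500L),
                     pct_repeated = 0)
  feats <- data.frame(id = c("inE", "half", "inNE"), ftype = "gene",
                      start = c(100L, 401L, 601L), end = c(200L, 600L, 700L))
  ms <- map_segments(segs, feats)
  expect_equal(ms$per_feature$pct_essential, c(1, 0.5, 0))
  expect_equal(ms$per_feature$n_e_segments, c(1L, 1L, 0L))
  # a segment with no feature overlap reports non-annotated
  segs2 <- data.frame(start = c(1L, 2001L), end = c(1000L, 3000L),
                      label = c("E", "E"), length = c(1000L, 1000L),
                      pct_repeated = 0)
  ms2 <- map_segments(segs2, feats)
  expect_equal(ms2$per_segment$features[2L], "non-annotated")
})

test_that("window calibration finds the smallest admissible size", {
  # perfectly separated pools: E genes empty, NE genes dense
  set.seed(9)
  L <- 42000L
  e_genes <- data.frame(id = sprintf("e%d", 1:10), ftype = "gene",
                        start = seq(1L, 19000L, by = 2000L),
                        end = seq(1800L, 20800L, by = 2000L))
  ne_genes <- data.frame(id = sprintf("n%d", 1:10), ftype = "gene",
                         start = seq(21000L, 39000L, by = 2000L),
                         end = seq(21000L, 39000L, by = 2000L) + 1800L)
  ne_pos <- unlist(lapply(seq_len(nrow(ne_genes)), function(i) {
    idx <- ne_genes$start[i]:ne_genes$end[i]
    idx[runif(length(idx)) < 0.9]
  }))
  s <- tn_sample(sort(ne_pos), rep(3L, length(ne_pos)))
  cal <- calibrate_window(s, e_genes, ne_genes, L,
                          sizes = c(3L, 15L, 31L), n_windows = 400L,
                          seed = 10)
  expect_equal(cal$curve$error, rep(0, 3))
  expect_equal(cal$chosen_w, 3L)

  # an impossible tolerance fails explicitly
  expect_error(calibrate_window(s, e_genes, ne_genes, L, sizes = 31L,
                                n_windows = 200L, tol = 0, seed = 10),
               "tolerance")
  expect_true(is.na(calibrate_window(s, e_genes, ne_genes, L, sizes = 31L,
                                     n_windows = 200L, tol = 0, seed = 10,
                                     on_fail = "na")$chosen_w))
})
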