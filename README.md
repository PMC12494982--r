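# tnseqr

Quantitative gene essentiality from serial-passage transposon insertion
sequencing (Tn-seq), for bacteria with small genomes where insertion
coverage approaches saturation.

Pooled transposon mutant libraries are sequenced after successive rounds of
growth selection ("passages"): insertions that disrupt important loci
deplete, insertions in dispensable sequence persist. `tnseqr` turns the
resulting position-to-read-count tables into

* **insertion calls** from inverted-repeat (IR) tagged reads, with ambiguous
  (repeat-region) placements discarded and reported;
* **linear densities** (LD = distinct inserted positions / region length in
  bp) with 21-bp repeat masking of the genome, plus RPKM;
* **essentiality classes** by an unsupervised 1-D Gaussian mixture over gene
  LDs — components ordered by mean map to E (essential), F1
  (quasi-essential), F2 (quasi-non-essential) and NE (non-essential), with
  AIC/BIC tables for choosing the component count;
* **fitness decay trajectories**: per-passage LD normalized by a gold set of
  known NE genes, clustered by k-means with a distortion elbow, and
  quantified by the trapezoidal area under the curve
  (AUC = ∫ LD_norm(p) dp over the passage grid);
* **E/NE genome segmentation** with a calibrated 31-bp sliding window,
  independent of any annotation — including the window-size calibration that
  bounds the probability of miscalling an essential window;
* **library comparisons** between promoter-bearing (P) and
  terminator-bearing (T) transposons (one-tailed AUC t-tests, fold changes);
* **enrichment statistics** for positions selected over passages: TMM count
  normalization, one-tailed tests with Bonferroni control, annotation
  categories, whole-gene tests with hottest-insertion subtraction, COG
  hypergeometric enrichment with Benjamini–Hochberg adjustment, and
  binding-site accessibility tests;
* a fully parameterized **synthetic library generator** (genome, annotation,
  IR-tagged FASTQ, passage series with class-specific decay and P/T
  regulatory asymmetries) so the entire pipeline is testable without any
  sequencing download.

## Worked example

```r
library(tnseqr)
cfg <- sim_config(genome_length = 120000, n_genes = 100, seed = 42)
genome <- generate_genome(cfg)
annot  <- generate_annotation(cfg, genome)
genes  <- annot[annot$ftype == "gene", ]
mask   <- compute_repeat_mask(genome)          # 21-bp repeat labeling

passages <- c(1, 2, 3, 4, 6, 8, 10)
P <- simulate_library(cfg, genome, annot, "P", passages, replicates = 2)
T <- simulate_library(cfg, genome, annot, "T", passages, replicates = 2)

# merged PT passage-1 dataset with 5% read-count trimming
pt1 <- merge_samples(c(P[grep("_p1_", names(P))], T[grep("_p1_", names(T))]))
#> <tn_merged> 4 samples, trim 0.05: 74,059 positions, 56,155,758 reads

m   <- linear_density(pt1, genes, mask = mask)
fit <- fit_mixture(setNames(m$ld, m$feature_id), k_candidates = 1:6, seed = 1)
#> <tn_mixfit> n=100, candidates k={1,2,3,4,5,6}, selected k=4
#>  k    loglik        aic        bic
#>  1 -45.44478   94.88955  100.09989
#>  2 -16.48567   42.97134   55.99719
#>  3 134.23303 -252.46607 -231.62471
#>  4 247.12348 -472.24696 -443.59009
#>  5 248.73591 -469.47182 -432.99944
#>  6 257.09944 -480.19888 -435.91098
calls <- classify(setNames(m$ld, m$feature_id), fit, k = 4)
table(calls$category)
#>  E F1 F2 NE
#> 25 25 25 25
mean(calls$category == genes$true_class)
#> [1] 1
```

The BIC improvement collapses after four components, and the four hard
calls recover the generator's planted classes exactly. Decay clustering
tells the same story dynamically — cluster mean AUCs order E < F1 < F2 < NE
(an NE gene tracking the gold normalizer for 9 passages has AUC ≈ 9):

```r
byp <- lapply(setNames(as.character(passages), passages), function(p)
  merge_samples(c(P[grep(paste0("_p", p, "_"), names(P))],
                  T[grep(paste0("_p", p, "_"), names(T))])))
prof <- build_trajectories(byp, genes, gold = genes$id[genes$gold_ne],
                           mask = mask)
km <- kmeans_decay(prof, seed = 1, min_cluster_size = 20)
km$k
#> [1] 4
round(tapply(km$clusters$auc, km$clusters$cluster, mean), 2)
#>    1    2    3    4
#> 0.00 0.35 2.97 9.00

seg <- segment_genome(pt1, genome, mask = mask, w = 31, seed = 1)
nrow(seg); sum(seg$length) == genome$length
#> [1] 161
#> [1] TRUE
table(filter_segments(seg)$label)
#>  E NE
#> 75 81
```

The same stages are scriptable through the pipeline CLI
(`simulate`, `call`, `metrics`, `classify`, `decay`, `segment`, `enrich`,
`report`), e.g.

```sh
Rscript -e 'tnseqr::tn_cli()' simulate --outdir run --seed 5
Rscript -e 'tnseqr::tn_cli()' metrics  --outdir run
Rscript -e 'tnseqr::tn_cli()' classify --outdir run --k 4
Rscript -e 'tnseqr::tn_cli()' report   --outdir run
```

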