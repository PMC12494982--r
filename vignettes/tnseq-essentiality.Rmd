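---
title: "Quantitative essentiality from serial-passage Tn-seq: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative essentiality from serial-passage Tn-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tnseqr)
```

# The measurement model

A saturating transposon mutagenesis experiment produces, per sample, a map
from genome position to the number of sequencing reads supporting an
insertion at that position. `tnseqr` treats three facts about such data as
foundational:

1. **Presence, not depth, carries the essentiality signal at passage 1.**
   The linear density of a region,
   $\mathrm{LD} = \frac{\#\ \text{distinct inserted positions}}{\text{region
   length (bp)}}$, is invariant to sequencing depth and is the primary
   statistic. Read counts matter later, for selection (enrichment) analyses.
2. **Repeated sequence is unmappable.** Any 21-bp window whose sequence
   occurs at least twice across the genome and its reverse complement is
   flagged; flagged bases are excluded from both numerator and denominator
   of per-feature LDs. The genome-wide coverage figure is conventionally
   quoted *without* repeat exclusion (insertions / genome length), and
   `linear_density()` exposes both conventions.
3. **Serial passaging converts essentiality into dynamics.** Roughly ten
   generations separate passages; insertions in costly loci deplete
   multiplicatively. Trajectories are normalized per sample by the mean LD
   of a curated gold set of known non-essential (NE) genes, removing
   sample-level coverage differences, so a neutral locus sits at 1 across
   the whole series.

## Essentiality classes by Gaussian mixture

Gene LDs in a saturated library are strongly multimodal: essential genes
near zero, non-essential genes near the saturation density, and
intermediate fitness genes between. `fit_mixture()` fits one-dimensional
Gaussian mixtures by EM (k-means++ seeding, 10 restarts, full per-component
variances, variance floor $10^{-6}\,\widehat{\sigma}^2$) for a range of
component counts and tabulates AIC/BIC. Components sorted by ascending mean
map to E < F1 < F2 < NE for $k=4$, or E < NE for $k=2$; hard calls take the
argmax posterior, with ties resolved toward the more essential class
(conservative for biology).

The automated model-size rule — take the largest $k$ whose BIC improvement
over $k-1$ is at least 2% of the 1→2 improvement — is a stated convention
standing in for visual elbow inspection; `classify()` accepts any fitted
$k$, so the selection is advisory, not binding. For regulatory and
structural elements the two-component model is used directly: empirically
the binary boundary separates E∪F1 from F2∪NE, which the test suite checks
on simulated data. A post-hoc stringency cut (`stringent_essential()`,
LD ≤ 0.4) narrows essential-regulatory candidates after classification; it
is deliberately not part of the classifier.

## Decay clustering and AUC

`build_trajectories()` assembles NE-normalized per-passage metrics; missing
passages are omitted from the grid, never imputed. The fitness summary is
the trapezoidal area under the trajectory. Two grids are first-class
defaults, because both are natural units of the experiment: genes use
passages (1, 2, 3, 4, 6, 8, 10) — a flat neutral trajectory integrates to
9 — while window/segment AUCs use passages 1–8 (`auc_trapz(range =
c(1, 8))`).

`kmeans_decay()` clusters trajectories with k-means, recording the
distortion (total within-cluster sum of squares) per candidate $k$. The
selected $k$ maximizes the relative distortion drop among candidates whose
smallest cluster still holds `min_cluster_size` (default 50) profiles; the
size constraint is what keeps the elbow from chasing noise splits, and a
manual override is supported. Features with more than 25% repeated sequence
are excluded before clustering — repeat exclusion leaves them with few,
mostly inserted, positions, which inflates their apparent densities and
distorts cluster shapes. Labels are re-ordered by ascending mean AUC so
cluster numbering is deterministic across runs.

The promoter-vs-terminator comparison (`compare_libraries_auc()`) uses
per-replicate AUCs: fold change `mean(AUC_P)/mean(AUC_T)` and a one-tailed
t-test in the direction of the observed fold change at α = 0.05. The test
is unpaired Welch by default with a paired option: with two replicates per
library, the data do not distinguish the variants, and the unpaired form is
the safer default when replicate pairing between libraries is arbitrary.

## Sliding-window segmentation

`segment_genome()` slides a `w`-bp window at step 1, computes window LD on
non-repeated bases ("informative" windows are those with at least one
non-repeated base; fully repeated windows carry no evidence and inherit
the default E label unless covered by an NE window), and classifies windows
E/NE. The two-component mixture is reduced to the LD value where the two
component densities cross, and windows above this cutoff are NE. Reducing
the classifier to a threshold has two virtues: it makes window calls
monotone in the data (for a fixed cutoff, adding insertions can only move
territory from E to NE, a property the tests verify), and it makes the
classifier portable — the `cutoff` attribute of a segmentation can be
reused on another dataset.

A base is NE if **any** covering window is NE (maximizing NE coverage is
conservative for declaring essentiality; a majority rule is available).
Remaining bases are E; maximal same-label runs tile the genome exactly.
Reported E segments must cover ≥ 5 bp with < 10% repeated sequence;
the unfiltered tiling is kept for coordinate bookkeeping.

The window size is not arbitrary: `calibrate_window()` samples windows from
genes of known class, classifies the pooled window LDs unsupervised, and
records the probability of miscalling an essential-gene window as NE,
choosing the smallest size below tolerance (default 5%). At the default
simulated densities, 31 bp is comfortably inside the tolerance; the
calibration exists so that a user with sparser libraries can discover they
need wider windows.

N- and C-terminal tolerance (`termini_analysis()`) reads the reach of NE
segments into each gene end (strand-aware) in amino acids (bp/3, floored),
and optionally compares terminus AUC to whole-gene AUC.

## Enrichment over passages

Positive selection is assessed only at positions detected in the first and
last passage of both replicates (`valid_positions()`). Counts are scaled by
trimmed-mean-of-M-values factors (`tmm_factors()`; 30% M-trim, 5% A-trim,
computed against the first passage-1 replicate). The implementation uses an
*unweighted* trimmed mean: M and A depend only on count proportions, so the
factors are exactly scale-equivariant — multiplying a sample's counts by a
constant multiplies its factor by the same constant — a property the
delta-method precision weighting of some TMM implementations gives up for
a small variance gain. The suite checks agreement with the reference edgeR
implementation (unweighted mode) to 1%.

Per-position tests are one-tailed (passage 10 > passage 1 — the direction
is fixed a priori by the selection design), Bonferroni-corrected over the
positions tested; positions with zero passage-1 mean cannot form a ratio
and are reported untested. Whole-gene enrichment subtracts the three
insertions with the highest last-passage reads before testing, so a verdict
requires a coding-sequence-wide shift rather than a few hot sites. COG
enrichment uses the upper-tail hypergeometric probability per category with
Benjamini–Hochberg adjustment across categories. Binding-site accessibility
compares each site with same-length flanks by a one-tailed paired t-test
across sites (site < flanks).

# The synthetic generator: a stated world

`sim_config()` fixes the world the analyses assume; its defaults are chosen
once and are not tuning knobs.

| parameter | default | meaning |
|---|---|---|
| `density_p1` | E 0.01, F1 0.15, F2 0.45, NE 0.92 | per-base insertion probability at passage 1; NE matches the near-saturation density observed in genome-reduced bacteria |
| `decay_rate` | E 0.05, F1 0.3, F2 0.7, NE 0.97 | multiplicative survival per passage, producing the four canonical decay shapes |
| `termini_frac` | 0.02 | fraction of an E gene length insertable at each end (tolerant termini of essential genes are a few percent of protein length) |
| `read_mu`, `read_dispersion` | 267.1, 0.5 | negative-binomial reads per insertion with a floor of 2 (single-read insertions are discarded downstream, so the generator never emits them) |
| `p_regulatory_bias` | 0.25 | extra per-passage retention for P-library insertions upstream of E genes |
| `class_fractions` | ¼ each | equal classes keep every class well-populated at the n = 100–400 scale used in tests (real genomes are NE-heavier; the proportions are a property of the organism, not of the method) |

Design choices worth stating explicitly:

* **E genes are insertable only in their termini**, at the E per-base
  density; bodies are structurally zero. This implements tolerant
  N/C-termini without modeling protein domains. Tests that probe terminus
  *detection* raise the terminus density to NE-like values, since a
  terminus only becomes visible to the window classifier when it is
  actually inserted.
* **Replicates are thinnings of a shared passage-1 master pool** (survival
  `decay_rate^(passage-1)`, independent per replicate), so
  reproducible-insertion logic has genuinely shared positions to find.
* **Intergenic sequence behaves like NE.** Positions upstream of essential
  genes (150 bp, strand-aware) decay at the F2 rate in both libraries —
  perturbing the regulation of an essential gene is costly — and the P
  library adds `p_regulatory_bias` to the retention probability there.
  This is the minimal mechanism that reproduces the observed P/T asymmetry
  in regulatory regions.
* **Strand is ignored for insertions**; every metric in the package is
  strandless.
* The chromosome is treated as **circular** by `emit_reads()` /
  `call_insertions()` (anchors wrap through the origin), matching bacterial
  topology; a truncating mode exists.

What the generator does **not** emulate: sequence composition (GC skew,
codon usage, the mild TA dinucleotide preference of the transposase),
repeats long enough to defeat read mapping beyond the 21-mer mask,
replication-origin distance effects on coverage, and batch effects between
sequencing runs. A green test therefore establishes that the algorithms
recover the structure they assume — not that real libraries satisfy those
assumptions.

# Numerical conventions

* Coordinates are 1-based closed intervals everywhere (GFF3 convention);
  BED export converts explicitly.
* Repeat labeling marks all 21 bases covered by a repeated window; a
  `mark = "start"` policy (label only window starts) is available, since
  the covering choice is a policy, not a fact.
* Merging trims each sample's top and bottom 5% of insertions by read
  count (type-7 quantiles, strict inequalities, so boundary ties are
  retained) before taking the union of positions.
* The insertion position convention is the first genomic base 3′ of the
  IR junction (for reverse-strand placements, the base adjacent to the tag
  is the high end of the matched interval). Any consistent convention
  suffices because all metrics are counts over intervals.
* EM convergence: relative log-likelihood change < 1e-8, ≤ 500 iterations;
  degenerate (all-identical) inputs fall back to a single component with a
  warning rather than failing.
* Posterior ties break toward the more essential class; k-means cluster
  labels are fixed by ascending mean AUC; all stochastic steps take
  explicit seeds and restore the caller's RNG state.

# Known limitations

* The GC-composition correction used by some pipelines is exposed only as
  a hook (repeat-masked densities are computed without positional
  weighting): the published correction is not reconstructible from its
  description, and silently approximating it would be worse than omitting
  it.
* With two replicates per condition, the per-position t-tests have one
  degree of freedom; Bonferroni control is honest but conservative, and
  verdicts at that replication level lean heavily on tight replicate
  agreement.
* The window classifier is refit per dataset by default. Cross-dataset
  comparisons of E/NE territory should reuse a single cutoff (see
  `segment_genome(cutoff = )`), otherwise threshold drift can dominate
  small differences.
* The automated elbow rules (BIC for the mixture, distortion for k-means)
  are conventions that make the defaults deterministic; they are designed
  to be overridden by inspection, not trusted blindly.
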