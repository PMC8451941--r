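---
title: "Models and design choices in duoReg"
author: "duoReg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in duoReg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

duoReg implements the computational core of a common situation in
regulatory genomics: two transcription factors — here the orphan nuclear
receptors Esrrb and Nr5a2 in mouse embryonic stem cells — recognise the
same DNA element and must be disentangled by sequence preference,
co-binding dependence and downstream transcriptional consequences. This
vignette explains each statistical component, the tunable parameters, the
synthetic data the package uses to validate itself, and the design
choices that were genuinely open.

## The motif machinery

Both receptors bind the 9-bp extended half-site `TCAAGG(T/C)CA`
monomerically; the seventh base discriminates an Esrrb preference (T)
from an Nr5a2 preference (C). Three scanners serve this analysis:

* `scanConsensus()` reports every window, on either strand, within a
  Hamming distance of 0 or 1 of a variant consensus. `N` bases never
  match a constrained position (a conservative choice: an ambiguous base
  is evidence of nothing).
* `scanTrimmedHalfsite()` matches `TCAAGG?CA` with *complete freedom* at
  position 7: that base is excluded from the mismatch count and reported
  literally. This pins the discriminating base: with plain 1-mismatch
  matching of the full variant consensi, a T-variant site with a
  mismatch at position 7 would masquerade as a C site. Whether the
  original analyses tolerated a mismatch at position 7 itself is not
  documented; our pinned rule is the stricter reading and is flagged
  here as a choice.
* `scorePwm()` computes the standard summed log2-odds of the
  pseudocount-adjusted position probabilities against a background, for
  every window on both strands, with no threshold. Thresholding (for
  example `filterAboveMedian()`, which keeps hits scoring strictly above
  the median of their motif's hit set) is deliberately a separate step.

All hit coordinates are 0-based offsets of the leftmost matched base on
the + strand of the region, whatever the hit strand; one convention
keeps every downstream distance computation simple. Overlapping hits are
all reported — no greedy masking, since none is documented.

Region variant classes (`classifyRegionsByVariant()`) are `T_only`,
`C_only`, `both`, `none`, from the seventh-base labels of
trimmed-half-site hits with at most one mismatch elsewhere. The
seventh-base preference profile (`seventhBaseProfile()`) computes T/C
hit frequencies in windows of regions ranked by the binding ratio
`log2((Esrrb RPM + 0.5) / (Nr5a2 RPM + 0.5))`; the 0.5 RPM pseudo-value
guards empty regions, and windows may be sliding (default, step 1) or
tiled. Window size (default 100 regions) and the sliding/tiled choice
are not dictated by anything in the underlying analyses; both are
exposed.

## Peak logic and the count model

`reproduciblePeaks()` keeps the genomic runs covered by peaks in at
least `minReplicates` replicates and reports, per run, the union-span of
the contributing peaks, with the core run kept in metadata. Reporting
the union-span keeps summit context; reporting one region per core run
(rather than merging overlapping spans) keeps the output in one-to-one
correspondence with the reproducibly covered runs, which makes the
operation exactly testable against a base-level coverage sweep.
`mergePeakSets()` merges per-factor peak sets and carries one logical
flag per input set, from which co-binding (Venn) counts follow.
Blacklist exclusion removes regions overlapping an excluded interval by
one base or more.

Differential binding and expression use a self-contained
negative-binomial Wald test (`differentialTest()`), with variance
`mu + alpha * mu^2`:

* size factors by median-of-ratios (rescaled to geometric mean one),
  with total-count fallback; a `sizeFactors = "libsize"` option uses the
  recorded library sizes instead. Median-of-ratios assumes most units
  are unchanged between conditions — on data where the majority of
  regions genuinely shift (as in the synthetic class presets, where
  every class responds to the double depletion) it absorbs part of the
  shift, so the pipeline's differential stage on those presets uses the
  known library sizes. This is a property of ratio normalisation, not of
  this implementation.
* per-unit method-of-moments dispersion from within-condition variances,
  shrunk with weight 0.5 towards a trended `a0 + a1/mu` fit; trend-only
  (and flagged) when a condition has a single replicate;
* a per-unit NB GLM with fixed dispersion and log size-factor offsets;
  the Wald statistic for the condition coefficient is referred to a t
  distribution with (samples − 2) degrees of freedom. With triplicates
  the plain normal reference is anticonservative; the t reference keeps
  the empirical type-I error near nominal (measured in the acceptance
  suite: within [0.01, 0.10] at nominal 0.05). With a 1-vs-1 design the
  GLM is saturated and an analytic Wald with delta-method variance
  `(1/mu + alpha)/m` is used instead;
* Benjamini–Hochberg correction; calls `up`/`down` at FDR < 0.05 for
  binding by default (expression filtering uses FDR < 0.01 with the
  strict |FC| > 1.5 and ≥ 20-raw-counts-in-all-replicates-of-a-condition
  rules, in `deFilter()`).

The test is declared pluggable: it matches the contract of the
established count-based tools, and the test suite cross-checks its fold
changes against DESeq2 on shared input.

## Occupancy dependence classes

Occupancy rows are replicate means of library-normalised counts per
(TF, condition), max-normalised per TF so the condition of maximal
binding is one (`maxNormalise()`; all-zero TF rows are flagged and set
to zero). Clustering uses Euclidean K-means on the Oct4/Sox2/Nanog
columns only — the dependence classes are defined by the response of the
pluripotency factors, not of the receptors themselves. K-means runs
Lloyd iterations (via `stats::kmeans`) from k-means++ seeds, best of 10
restarts, 300-iteration cap; labels are renumbered by increasing cluster
mean over the double-depletion columns, making the numbering
deterministic and initialisation-invariant.

The number of classes is chosen by `selectK()`, a formalisation of
"the first k at which enrichment is robust": for each candidate k and
each of R = 5 reseeded clusterings, proximity enrichment of each
differential-response gene set is computed around each cluster; a
clustering is robust when every cluster is enriched (p < 1e-3 at some
distance) **and every response gene set is the best match of at least
one cluster**. k is robust when at least r = 4 of 5 clusterings are, and
the first robust k wins. The coverage requirement is the load-bearing
part: enrichment presence alone is satisfied by any k ≥ 2 once clusters
merge linked classes (a merged cluster is still strongly enriched), so a
rule based only on per-cluster enrichment would always select the
smallest k. Requiring every response class to be resolved by its own
best-matching cluster makes the selected k track the number of
distinctly linked classes, which is what the procedure is for. All
thresholds (1e-3, 4/5) are exposed and reported.

## The two enrichment statistics

**Motif-pair spacing.** Distances are measured between motif centres
(`offset + floor(width/2)`) for all intra-region pairs of A-hits and
B-hits; self-pairs are excluded when A and B are the same set, distinct
overlapping hits are kept, and pairs never cross regions. Distances are
binned (default 10 bp over [0, 500] bp). The null keeps everything about
the hit lists — per-region counts, strands, motif widths — and re-draws
only positions, uniformly among the placements that fit the region; the
expected histogram is the mean over 100 seeded shuffles. Per bin the
p-value is the Poisson right tail `P(X >= observed)` at the expected
rate; a bin with zero expectation and positive observation is reported
as p = 0 and flagged degenerate. Under-flowing p-values are clamped at
1e-300 before `-log10`, and the clamp is recorded in the curve metadata.

**Gene proximity.** For a distance grid x (default 50 log-spaced points
over [1, 1e6] bp), with N genes in the universe, K within x of the
region set, n differentially expressed and k differentially expressed
within x, the p-value is the hypergeometric right tail `P(X >= k)`.
The TSS–region distance is zero inside a region and otherwise the count
of bases to the nearest edge, same chromosome required, with inclusion
at exactly x. The gene universe is the annotation that passed the
expression count filter — the DE universe — a declared choice, since
"all genes" is ambiguous between annotated and expressed.

## Gaussian-process trend and cooperativity

`gpTrend()` is exact GP regression with an RBF kernel plus independent
noise on a mean-centred response, used to smooth the Z-scored binding
fold change against the C-versus-T motif composition of region windows.
Initial hyperparameters are lengthscale = x-range/5, signal variance =
var(y), noise variance = var(y)/10; marginal-likelihood maximisation
uses L-BFGS-B on log parameters with three seeded restarts. If the
kernel matrix is numerically singular, diagonal jitter grows in decade
steps from 1e-10 to 1e-4 × signal variance (recorded in the fit) before
erroring. RBF Gram matrices become ill-conditioned when the lengthscale
is large relative to the point spacing; in the noise-free limit the
posterior interpolates to machine precision only in the well-conditioned
regime, which the tests exercise explicitly. The pipeline fits the trend
on tiled (non-overlapping) rank windows: the points are then
approximately independent and the exact solve stays small.

Cooperativity: for regions with exactly one recognisable half-site
(`singleSiteRegions()`), `additivityTest()` computes
`delta = fc_double - (fc_1 + fc_2)` on log2 fold changes and tests
`median(delta) < 0` with a one-sided Wilcoxon signed-rank test.
"Greater-than-additive" has no canonical formula; additivity on the log
scale (fold changes multiply) with a rank test (no normality assumption
on per-region fold-change estimates) is our declared operationalisation,
and the test suite checks it against a sign-flip permutation oracle.
`foldchangeCorrelation()` reports the Pearson correlation of per-gene
fold changes across two contrasts over the union (default) or
intersection of their DE calls.

## The synthetic study

`syntheticStudy()` builds, deterministically from one seed, a complete
study with known truth. What it emulates: i.i.d. background sequence at
a chosen GC content with motif strings overwritten at recorded
positions (unambiguous truth, no blending); negative-binomial counts
with shared dispersion alpha = 0.1 (a typical ChIP/RNA-seq value),
baseline mean 100, per-sample library factors in [0.8, 1.2], and
class-by-condition log2 effects; genes whose TSS placement and DE status
are tied to region classes. What it does not emulate: read-level
artefacts, fragment-length and GC bias, peak-calling noise,
copy-number structure, correlated dispersions, and clustered (non-i.i.d.)
genomic background. Passing tests therefore demonstrate correctness of
the statistics and recoverability of planted structure under the stated
model, not robustness to those real-data artefacts.

Preset conditions (fixed as the package's study conditions):

* **null** — 2 chromosomes × 1 Mb, 2000 regions × 400 bp, no planted
  motifs, no effects, no gene links; the calibration condition.
* **spacing** — as null, plus one half-site per region and a 15-bp
  Oct/Sox composite planted at a 50 bp centre distance (± 5 bp uniform
  jitter) in 30% of regions.
* **classes** — five equal occupancy classes; Oct4/Sox2/Nanog log2
  effects per class and depletion condition of (class 1) −2 under −E,
  (2) −2 under −N, (3) −0.75/−0.75/−2.5, (4) −1.5/−1.5/−3, (5)
  +1/+1/+2; receptors collapse (−3) in their own depletions; 3
  replicates × 4 conditions; 1000 genes with five 60-gene DE sets, each
  linked (80% within 5 kb) to its class. Class separations of ≥ 1 log2
  unit make recovery achievable at the chosen noise, without being
  trivial.
* **full** — classes plus sequence on 2 × 25 Mb: a linear T-to-C
  seventh-base gradient along regions coupled to a ±1.5 log2
  Esrrb/Nr5a2 binding-ratio effect, one or two half-sites per region
  (80/20), Oct/Sox spacing plants, the greater-than-additive class-3
  double depletion (delta = −1), and gene links for classes 1–4 only —
  class 5 is the unlinked decoy.

The class presets sit on 2 × 25 Mb coordinates rather than the 1 Mb
chromosomes of the sequence presets: with 2000 × 400 bp regions on 2 Mb,
every gene would be within ~1 kb of some region and proximity
enrichment would saturate before the 5 kb link distance could be seen.
At 50 Mb the background within-5 kb rate is ~0.4, leaving the planted
enrichment recoverable in the 1–50 kb range. The sequence presets keep
the smaller genome (placement density does not matter for within-region
spacing statistics, and scanning stays fast).

Problem sizes throughout (2000 regions, 1000 genes, 20 calibration
replicates, 100 shuffles) were chosen so each stage completes in seconds
to a few minutes while leaving planted-truth recovery statistically
comfortable.

## Pipeline and reproducibility

`runPipeline()` chains simulate → scan → diff → classify → pairdist →
proximity → trend → coop from one YAML config with a single top-level
seed; per-stage seeds are derived by stage-name hashing, so one knob
reproduces everything. Every table is written with six significant
digits, making repeated runs byte-identical; a manifest of MD5 digests
is emitted, plus an error manifest naming the failed stage on partial
failure. With `resume = TRUE`, the first stage with a missing output is
located, earlier results are reloaded from disk, and only the remainder
is recomputed. The package deliberately has no shell entry point: its
users drive it from R, and the exported functions are the interface.

## Known limitations

* The NB test's t-reference Wald is a pragmatic small-sample
  calibration, not an exact test; extremely low counts with 2–3
  replicates remain hard, as for all tools of this family.
* The robustness rule in `selectK()` is one defensible formalisation of
  a qualitative published criterion; alternatives (stability indices,
  silhouette) are out of scope.
* The randomised spacing background repositions hits uniformly within
  regions; sequence-composition-matched backgrounds are not modelled.
* The GP fit is exact and O(n³); it is meant for tens-to-hundreds of
  trend points, not thousands (the pipeline tiles windows for this
  reason).
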